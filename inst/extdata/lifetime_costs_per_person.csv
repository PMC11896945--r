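gender,level,category,cost_thousands
women,inactive,hc_dementia,19.7
women,inactive,hc_other,41.2
women,inactive,sc_dementia,9.2
women,inactive,sc_other,7.4
women,inactive,unpaid_care,2.23
women,low,hc_dementia,13.8
women,low,hc_other,44.2
women,low,sc_dementia,6.5
women,low,sc_other,8.8
women,low,unpaid_care,1.63
women,some,hc_dementia,14.3
women,some,hc_other,44.8
women,some,sc_dementia,6.6
women,some,sc_other,9.1
women,some,unpaid_care,1.63
women,meets,hc_dementia,14.1
women,meets,hc_other,45.7
women,meets,sc_dementia,6.6
women,meets,sc_other,9.5
women,meets,unpaid_care,1.63
men,inactive,hc_dementia,19.2
men,inactive,hc_other,34.1
men,inactive,sc_dementia,8.9
men,inactive,sc_other,3.5
men,inactive,unpaid_care,2.18
men,low,hc_dementia,13.3
men,low,hc_other,37.3
men,low,sc_dementia,6.2
men,low,sc_other,4
men,low,unpaid_care,1.58
men,some,hc_dementia,13.7
men,some,hc_other,38
men,some,sc_dementia,6.4
men,some,sc_other,4.2
men,some,unpaid_care,1.58
men,meets,hc_dementia,13.5
men,meets,hc_other,39
men,meets,sc_dementia,6.3
men,meets,sc_other,4.3
men,meets,unpaid_care,1.58
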