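gender,age_band,level,percent
women,16-24,meets,57
women,16-24,some,14
women,16-24,low,4
women,16-24,inactive,24
women,25-34,meets,66
women,25-34,some,14
women,25-34,low,6
women,25-34,inactive,15
women,35-44,meets,66
women,35-44,some,14
women,35-44,low,5
women,35-44,inactive,15
women,45-54,meets,67
women,45-54,some,13
women,45-54,low,4
women,45-54,inactive,15
women,55-64,meets,58
women,55-64,some,11
women,55-64,low,4
women,55-64,inactive,27
women,65-74,meets,55
women,65-74,some,12
women,65-74,low,7
women,65-74,inactive,26
women,75+,meets,35
women,75+,some,13
women,75+,low,5
women,75+,inactive,47
men,16-24,meets,72
men,16-24,some,8
men,16-24,low,1
men,16-24,inactive,18
men,25-34,meets,78
men,25-34,some,7
men,25-34,low,4
men,25-34,inactive,11
men,35-44,meets,78
men,35-44,some,8
men,35-44,low,3
men,35-44,inactive,11
men,45-54,meets,72
men,45-54,some,10
men,45-54,low,2
men,45-54,inactive,16
men,55-64,meets,69
men,55-64,some,10
men,55-64,low,2
men,55-64,inactive,20
men,65-74,meets,65
men,65-74,some,11
men,65-74,low,4
men,65-74,inactive,19
men,75+,meets,41
men,75+,some,11
men,75+,low,4
men,75+,inactive,43
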