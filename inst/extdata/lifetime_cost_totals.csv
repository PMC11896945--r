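gender,level,total_thousands
women,inactive,79.76
women,low,74.93
women,some,76.43
women,meets,77.53
men,inactive,67.88
men,low,62.38
men,some,63.88
men,meets,64.68
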