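gender,scenario,rel_increase
women,scenario1,0.403
men,scenario1,0.364
women,scenario2,1.145
men,scenario2,0.771
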