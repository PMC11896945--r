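measure,baseline,scenario1,scenario2
women,2.79,4.0,6.0
men,8.89,12.1,15.8
absolute_gap,6.1,8.1,9.8
relative_gap,3.3,3.0,2.6
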