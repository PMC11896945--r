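level,rr
inactive,1.0
low,0.65
some,0.65
meets,0.62
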