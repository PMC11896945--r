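scope,gender,baseline,scenario1,scenario2
dementia_related,women,568.77,567.12,566.25
dementia_related,men,522.13,519.13,517.69
dementia_related,total,1090.91,1086.25,1083.94
total,women,1836.48,1835.75,1835.25
total,men,1489.57,1490.20,1488.88
total,total,3326.05,3325.95,3324.13
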