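scope,gender,level,baseline,scenario1,scenario2
dementia_related,women,inactive,140.87,135.34,132.55
dementia_related,women,low,24.37,27.38,28.83
dementia_related,women,some,71.50,69.80,68.78
dementia_related,women,meets,332.03,334.60,336.09
dementia_related,men,inactive,105.74,93.06,89.14
dementia_related,men,low,11.61,19.13,21.38
dementia_related,men,some,43.70,39.95,38.73
dementia_related,men,meets,361.07,366.99,368.44
total,women,inactive,360.32,346.17,339.02
total,women,low,83.11,93.36,98.31
total,women,some,242.20,236.46,233.02
total,women,meets,1150.85,1159.76,1164.90
total,men,inactive,236.69,208.30,199.53
total,men,low,34.29,56.50,63.13
total,men,some,128.58,117.55,113.96
total,men,meets,1090.01,1107.85,1112.25
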