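bsa_low,bsa_high,dose_mg
1.2000,1.3625,1500
1.3625,1.5250,1650
1.5250,1.6875,1800
1.6875,1.8500,1950
1.8500,2.0125,2100
2.0125,2.1750,2250
2.1750,2.3375,2400
2.3375,2.5000,2550
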