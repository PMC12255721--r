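ligand,cone_angle,electronic_parameter,buried_volume,logP
PPh3,145,2068.9,29.6,3.7
PCy3,170,2056.4,32.2,6.0
XPhos,256,2061.1,47.5,8.1
SPhos,240,2062.3,44.8,6.3
dppf,99,2066.7,26.1,5.2
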