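group,cut,beta0,beta1,beta2,mae,r2
I,shoulder_blade,0.7503,0.0586,-0.0033,0.16,0.173
I,shoulder_picnic,-0.6278,0.1438,-0.0283,0.23,0.385
I,loin,-1.1656,0.1156,0.0520,0.23,0.348
I,belly,-3.3129,0.2122,0.0657,0.58,0.200
I,ham,0.2182,0.2188,-0.0044,0.51,0.210
II,shoulder_blade,0.4320,0.0607,0.0030,0.16,0.488
II,shoulder_picnic,-0.6909,0.1427,-0.0207,0.24,0.702
II,loin,-0.9945,0.1141,0.0500,0.23,0.684
II,belly,-3.1669,0.2098,0.0696,0.59,0.506
II,ham,0.5907,0.2160,-0.0115,0.52,0.518
III,shoulder_blade,0.4396,0.0601,0.0046,0.17,0.896
III,shoulder_picnic,-0.6446,0.1411,-0.0168,0.25,0.864
III,loin,-1.0174,0.1155,0.0466,0.24,0.865
III,belly,-3.2610,0.2108,0.0708,0.59,0.776
III,ham,0.5883,0.2151,-0.0105,0.53,0.757
IV,shoulder_blade,0.2991,0.0609,0.0060,0.18,0.896
IV,shoulder_picnic,-0.7132,0.1407,-0.0137,0.27,0.940
IV,loin,-0.9785,0.1164,0.0430,0.28,0.941
IV,belly,-3.0578,0.2111,0.0633,0.63,0.909
IV,ham,0.2460,0.2178,-0.0103,0.58,0.897
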