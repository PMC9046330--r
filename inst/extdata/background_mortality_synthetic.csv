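age,q_annual
60,0.00648
61,0.00700
62,0.00757
63,0.00824
64,0.00898
65,0.00980
66,0.01070
67,0.01172
68,0.01288
69,0.01419
70,0.01568
71,0.01737
72,0.01930
73,0.02149
74,0.02399
75,0.02683
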