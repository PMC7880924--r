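age,qx
65,0.0126
66,0.013559
67,0.014606
68,0.015746
69,0.016991
70,0.018347
71,0.019827
72,0.02144
73,0.0232
74,0.025119
75,0.027211
76,0.029493
77,0.031981
78,0.034695
79,0.037654
80,0.040881
81,0.0444
82,0.048238
83,0.052422
84,0.056986
85,0.061963
86,0.06739
87,0.073308
88,0.079762
89,0.0868
90,0.094475
91,0.102845
92,0.111972
93,0.121925
94,0.132779
95,0.144616
96,0.157524
97,0.1716
98,0.18695
99,0.20369
100,0.221944
101,0.241851
102,0.263559
103,0.287232
104,0.313048
105,0.3412
106,0.3719
107,0.405379
108,0.441888
109,0.481701
110,0.525118
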