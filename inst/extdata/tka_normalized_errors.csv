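volunteer,error_before,error_after
1,1,0.06
2,1,0.09
3,1,0.11
4,1,0.07
5,1,0.05
6,1,0.04
7,1,0.08
8,1,0.03
9,1,0.11
10,1,0.09
11,1,0.03
12,1,0.08
13,1,0.05
14,1,0.06
15,1,0.04
16,1,0.08
17,1,0.06
18,1,0.03
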