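id,sex,age,bmi
1,Female,65,18.9
2,Female,60,21
3,Female,58,30
4,Female,66,20.3
5,Female,59,19
6,Male,70,22
7,Male,63,18.2
8,Female,72,23
9,Female,68,19.6
10,Male,74,21
11,Male,76,22.3
12,Male,65,18.9
13,Female,69,29
14,Male,77,30.5
15,Female,59,28
16,Male,78,23
17,Female,69,18
18,Female,76,21
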