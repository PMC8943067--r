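cluster,Vehicle,SP-A1
1,5,21
2,10,14
3,12,9
4,19,5
5,11,4
6,12,11
7,10,12
8,7,5
9,8,8
10,10,4
11,2,12
12,2,4
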