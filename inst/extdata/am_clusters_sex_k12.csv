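cluster,Female,Male
1,0,26
2,21,3
3,17,4
4,17,7
5,12,3
6,3,20
7,1,21
8,3,9
9,16,0
10,1,13
11,6,8
12,6,0
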