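cluster,Vehicle,SP-A1
1,6,5
2,1,16
3,23,0
4,5,9
5,14,6
6,0,10
7,6,2
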