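"concentration","days","emerged"
0,5,1
0,7,1
0,8,1
0,9,1
0,10,1
0,11,1
0,13,1
0,14,1
0,16,1
0,19,1
0,25,1
0.5,12,1
0.5,15,1
0.5,18,1
0.5,20,1
0.5,21,1
0.5,23,1
0.5,24,1
0.5,25,1
0.5,26,1
0.5,27,1
0.5,28,1
0.5,29,1
0.5,30,1
0.5,,0
0.5,,0
0.5,,0
0.5,,0
0.5,,0
0.5,,0
0.5,,0
0.5,,0
0.5,,0
0.5,,0
0.5,,0
0.5,,0
1,,0
1,,0
1,,0
1,,0
1,,0
1,,0
1,,0
1,,0
1,,0
1,,0
1,,0
1,,0
1,,0
1,,0
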