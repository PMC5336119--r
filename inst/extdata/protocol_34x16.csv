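src,sink
1,2
2,3
3,4
4,5
5,6
6,7
7,8
8,9
9,10
10,11
11,12
12,13
13,14
14,15
15,16
16,1
1,4
2,5
3,6
4,7
5,8
6,9
7,10
8,11
9,12
10,13
11,14
12,15
13,16
14,1
15,2
16,3
1,9
5,13
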