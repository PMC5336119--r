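src,sink
1,17
2,18
3,19
4,20
5,21
6,22
7,23
8,24
9,25
10,26
11,27
12,28
13,29
14,30
15,31
16,32
1,9
2,10
3,11
4,12
5,13
6,14
7,15
8,16
9,17
10,18
11,19
12,20
13,21
14,22
15,23
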