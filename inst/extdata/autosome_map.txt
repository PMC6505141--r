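1 286
2 269
3 223
4 214
5 204
6 192
7 187
8 168
9 166
10 181
11 158
12 175
13 126
14 119
15 141
16 134
17 128
18 117
19 107
20 108
21 62
22 74
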