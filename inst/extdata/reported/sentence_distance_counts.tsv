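distance	n
0	32409
1	8154
2	2646
3	1188
4	405
5	153
6	81
7	72
8	27
9	0
10	0
11	0
12	9
13	9
14	0
15	0
16	9
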