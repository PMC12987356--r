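2	5	3	8	7	12	8	13
4	8	15	12	0	0	9	0
7	0	14	1	12	9	14	14
7	2	4	1	9	11	0	13
1	6	9	7	15	5	9	11
11	6	11	3	13	6	12	1
9	14	9	1	3	13	6	11
1	13	8	14	6	1	11	10
0	7	6	8	0	3	9	1
10	13	15	1	12	9	14	10
10	10	10	7	0	14	8	10
5	6	8	14	9	4	6	12
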