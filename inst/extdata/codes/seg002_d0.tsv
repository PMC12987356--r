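7	15	4	1	0	13	9	9
0	5	5	15	4	1	6	7
12	5	10	15	5	14	8	9
11	5	2	1	3	8	6	11
3	0	14	3	13	7	12	7
7	12	12	13	5	0	12	7
3	15	9	2	12	10	7	13
15	3	5	5	13	6	11	15
7	2	10	11	1	9	9	0
2	12	6	12	1	12	13	3
10	2	2	15	15	15	14	4
5	14	3	5	13	8	14	9
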