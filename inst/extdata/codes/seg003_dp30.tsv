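3	9	14	2	7	5	1	0
8	13	9	3	5	12	1	6
1	12	3	5	7	14	7	13
9	3	5	12	4	15	10	2
4	11	10	5	1	13	14	5
2	7	15	2	8	4	12	15
0	15	9	7	3	9	1	13
8	10	7	9	5	12	6	12
10	14	7	1	8	11	6	4
15	7	11	13	6	14	3	4
5	12	14	12	3	6	12	7
1	5	11	6	0	7	13	5
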