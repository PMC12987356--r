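12	11	1	2	11	4	12	15
8	9	13	9	4	4	12	0
0	1	1	12	8	10	14	7
5	7	12	3	12	12	8	11
12	2	4	7	1	3	6	5
14	14	11	1	8	15	3	12
10	12	7	1	15	14	8	3
11	13	4	12	6	0	5	12
3	0	15	11	10	7	3	14
15	11	2	12	15	8	8	7
4	9	11	12	1	14	14	10
14	5	2	8	13	2	14	5
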