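10	11	9	10	1	9	6	8
4	1	3	2	15	9	13	5
0	12	2	7	11	3	4	8
1	11	15	3	4	15	4	2
5	9	6	8	5	2	15	1
15	6	4	12	5	7	9	5
5	12	6	2	2	11	15	11
2	13	13	6	4	13	9	10
14	14	8	13	7	3	9	13
11	0	4	7	11	9	5	14
4	8	5	8	3	8	14	15
2	13	1	1	11	0	8	0
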