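12	11	1	15	3	1	2	4
3	1	14	15	11	14	1	1
14	6	11	1	13	3	6	5
8	0	6	1	0	2	0	7
8	8	6	2	10	2	1	15
9	8	1	15	0	7	0	12
5	0	12	8	14	9	12	14
13	4	13	8	7	7	0	8
9	15	1	1	8	13	5	5
2	15	8	11	0	14	12	13
13	1	5	8	9	3	8	15
12	3	10	14	6	10	9	3
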