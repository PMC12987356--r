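10	9	6	5	9	0	4	3
7	15	10	3	11	1	0	11
9	12	8	14	0	10	12	4
13	3	9	4	15	11	1	9
6	14	0	4	13	5	6	8
4	13	15	5	6	12	5	5
4	3	3	10	12	10	15	3
7	13	0	9	15	14	6	8
5	0	4	12	14	14	13	3
3	3	7	4	2	13	15	5
15	3	1	15	7	8	2	14
6	13	9	3	13	1	10	11
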