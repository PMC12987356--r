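7	0	9	3	8	11	12	11
15	2	11	1	0	7	10	4
5	3	2	0	0	8	7	1
0	14	13	3	8	2	13	4
11	0	4	9	7	9	13	3
2	7	2	11	8	1	4	14
6	4	12	4	12	0	9	4
0	4	0	1	11	1	5	1
0	3	10	3	2	10	2	7
3	4	5	4	4	9	11	5
5	12	12	14	1	12	11	14
4	0	1	10	11	9	15	6
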