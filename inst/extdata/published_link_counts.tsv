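#chrom	links_microsat	links_radseq	links_gbs
1	13	15	42
2	6	6	23
3	6	4	28
4	3	4	24
5	15	13	22
6	9	20	37
7	11	6	31
8	4	7	42
9	5	8	31
10	3	4	14
11	0	5	36
12	7	6	26
13	11	7	34
14	6	9	24
15	5	8	27
16	3	7	23
17	6	1	52
18	8	7	32
19	3	1	42
20	7	3	21
21	3	6	16
22	4	7	42
23	6	7	33
24	8	9	38
25	3	3	31
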