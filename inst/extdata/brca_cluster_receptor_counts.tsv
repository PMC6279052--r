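cluster	n_patients	HER2	LuminalA	LuminalB	TNBC
1	193	12	105	25	51
2	56	6	5	0	45
3	98	1	82	12	3
4	55	2	45	7	1
5	80	6	47	24	3
6	29	0	20	7	2
7	46	1	28	17	0
other	201	6	84	23	3
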