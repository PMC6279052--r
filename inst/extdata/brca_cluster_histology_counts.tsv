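cluster	n_patients	IDC	ILC
1	274	212	62
2	79	78	1
3	134	73	61
4	85	73	12
5	93	89	4
6	55	36	19
7	54	51	3
other	182	154	28
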