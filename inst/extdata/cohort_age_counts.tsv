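age_group	CNTRL	SCZ	BD	MDD
(0-1]	26	0	0	0
(1-5]	12	0	0	0
(5-10]	15	0	0	0
(10-18]	37	0	0	0
(18-35]	59	25	16	14
(35-50]	6	59	34	18
(50-65]	56	25	21	13
(65-85]	33	33	2	1
(85-100]	9	3	0	0
Total	253	145	73	46
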