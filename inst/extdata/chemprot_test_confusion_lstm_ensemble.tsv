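class	CPR:1	CPR:2	CPR:3	CPR:4	CPR:5	CPR:6	CPR:7	CPR:8	CPR:9	CPR:10	negative
CPR:1	108	9	1	1	0	0	0	0	5	0	91
CPR:2	4	731	71	139	13	11	0	0	18	14	742
CPR:3	0	52	326	84	1	1	0	0	5	1	197
CPR:4	0	79	65	1107	2	9	0	0	35	7	363
CPR:5	0	18	4	9	102	11	0	0	0	0	54
CPR:6	0	21	0	8	12	198	0	0	1	0	53
CPR:7	0	9	4	6	0	2	0	0	0	0	4
CPR:8	0	5	1	2	0	0	0	0	7	0	10
CPR:9	0	52	3	8	0	0	0	0	274	5	302
CPR:10	0	23	16	30	0	4	0	0	9	94	91
negative	61	855	126	267	40	34	0	0	132	73	8437
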