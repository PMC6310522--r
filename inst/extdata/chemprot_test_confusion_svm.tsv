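class	CPR:1	CPR:2	CPR:3	CPR:4	CPR:5	CPR:6	CPR:7	CPR:8	CPR:9	CPR:10	negative
CPR:1	64	11	4	3	0	0	0	0	2	0	131
CPR:2	5	466	81	178	2	8	0	1	36	8	958
CPR:3	0	23	295	119	3	2	0	0	3	2	220
CPR:4	0	58	44	1175	0	3	0	0	7	7	373
CPR:5	0	14	1	19	74	3	0	0	1	3	83
CPR:6	0	16	0	2	4	154	0	0	1	1	115
CPR:7	0	7	1	5	0	2	0	0	2	0	8
CPR:8	0	0	1	5	0	0	0	0	0	0	19
CPR:9	0	10	4	28	0	0	0	0	233	1	368
CPR:10	0	30	17	54	0	0	0	0	2	53	111
negative	22	233	80	210	18	11	0	0	60	16	9375
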