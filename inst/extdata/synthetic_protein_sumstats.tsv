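SNP	CHR	POS	EA	OA	EAF	BETA	SE	P	N
rs1_1	1	1000000	A	G	     0.4375	0.01175871451	0.0321949097	0.7149744976	2000
rs1_2	1	1002000	T	G	    0.19775	0.03386494298	0.03923400683	0.3881570557	2000
rs1_3	1	1004000	C	G	      0.355	0.06034710574	0.03318860343	0.06916672873	2000
rs1_4	1	1006000	T	C	     0.3755	0.1188218642	0.03193388216	0.00020402086	2000
rs1_5	1	1008000	T	C	    0.24775	0.1839798137	0.03632696713	4.469762154e-07	2000
rs1_6	1	1010000	C	G	    0.35575	0.5022258132	0.03046103258	2.328259305e-57	2000
rs1_7	1	1012000	C	G	     0.2335	0.3088612275	0.03719930075	1.848233647e-16	2000
rs1_8	1	1014000	T	C	    0.17525	0.1894026088	0.04229189883	7.942653074e-06	2000
rs1_9	1	1016000	A	G	     0.4375	0.1714548158	0.03223611647	1.162013845e-07	2000
rs1_10	1	1018000	A	C	     0.0985	0.2418312839	0.05267297827	4.681654269e-06	2000
rs1_11	1	1020000	T	C	     0.4515	0.1831024516	0.03172928099	9.12591431e-09	2000
rs1_12	1	1022000	T	C	     0.4785	0.3780333705	0.03070231178	1.238374154e-33	2000
rs1_13	1	1024000	G	A	    0.36575	0.177485118	0.0326358241	6.036730985e-08	2000
rs1_14	1	1026000	T	C	    0.26725	0.08448505708	0.03609024776	0.01933319301	2000
rs1_15	1	1028000	A	G	    0.24775	0.1026892208	0.03673186189	0.005229166715	2000
rs1_16	1	1030000	A	G	    0.42475	0.1349198685	0.03197239038	2.553673707e-05	2000
rs1_17	1	1032000	A	G	    0.10775	0.2483257962	0.05045712544	9.291034508e-07	2000
rs1_18	1	1034000	A	C	    0.43975	0.3031783036	0.0307032882	1.741299672e-22	2000
rs1_19	1	1036000	T	G	    0.11075	0.1124905606	0.05052194941	0.0260872532	2000
rs1_20	1	1038000	A	G	    0.18025	0.02561092041	0.04106424389	0.5329093887	2000
rs1_21	1	1040000	T	C	    0.06675	0.01160384064	0.06365539878	0.8553724308	2000
rs1_22	1	1042000	G	A	     0.0975	-0.01653592655	0.05419891061	0.7603240332	2000
rs1_23	1	1044000	T	G	      0.352	-0.004304771835	0.0327027188	0.8952874764	2000
rs1_24	1	1046000	A	C	    0.43725	-0.007621128259	0.03169940564	0.8100303875	2000
rs1_25	1	1048000	A	G	     0.4165	-0.0310485693	0.0317757924	0.3286310432	2000
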