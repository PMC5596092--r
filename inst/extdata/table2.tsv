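conserved_srna	candidate	length	seq_start	seq_end	strand	fc_rpkm	mn_rpkm	sn_rpkm	mn_fc	sn_fc	opposite_strand
ctRNA (pMhu7653Ra)	MH_s1	62	2599	2660	-	1394.33	381.45	365.20	0.27	0.26	FALSE
ctRNA (pMhu7653Ra)	MH_s1	126	2602	2727	+	101.16	50.98	60.11	0.50	0.59	TRUE
ctRNA (pMhu7653Rb)	MH_s4	98	2418	2515	-	911.45	302.92	314.35	0.33	0.34	FALSE
ctRNA (pMhu7653Rb)	MH_s4	131	2344	2474	+	147.02	157.55	104.17	1.07	0.71	TRUE
tmRNA	MH_s19	90	3053513	3053602	-	163.27	72.76	70.51	0.45	0.43	FALSE
RNase	MH_s20	403	3136500	3136902	-	692.90	1039.98	1205.31	1.50	1.74	FALSE
6S RNA	MH_s32	140	5092499	5092638	-	1244.63	1253.26	1299.15	1.01	1.04	FALSE
4.5S RNA	MH_s40	289	6301885	6302173	+	523.54	883.04	859.06	1.69	1.64	FALSE
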