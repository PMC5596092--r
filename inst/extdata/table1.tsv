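candidate	strand	pred_start	pred_end	pred_length	igr_id	left_gene	left_strand	right_gene	right_strand	seq_start	seq_end	seq_length	gene	northern	opposite
MH_s1	-	2600	2657	58	IGR_Pa-3	MCHK_RS30880	+	MCHK_RS30885	+	2599	2660	62	RF262852|AP003017, ctRNA	no	2601-2727/+ (127)
MH_s2	+	4846	4927	82	IGR_Pa-5	MCHK_RS30885	+	MCHK_RS30890	-	4833	4906	74	RF401853|AE008135, AE009169; suhB	no	
MH_s3	-	61072	61423	352	IGR_Pa-50	MCHK_RS31140	-	MCHK_RS31145	-	61074	61262	189	un	yes	
MH_s4	-	2432	2496	65	IGR_Pb-1	MCHK_RS31790	+	MCHK_RS31795	+	2418	2515	98	RF262852|AP003017, ctRNA	no	2344-2474/+ (131)
MH_s5	+	27793	28144	352	IGR_Pb-19	MCHK_RS31915	+	MCHK_RS31920	+	27704	28144	441	RF01793, ffh	no	
MH_s6	-	58029	58284	256	IGR_G-46	MCHK_RS00260	-	MCHK_RS00265	+	no	no	no	un	no	
MH_s7	-	72421	72732	312	IGR_G-58	MCHK_RS00320	-	MCHK_RS00325	+	72492	72661	170	un	yes	
MH_s8	-	866178	866302	125	IGR_G-605	MCHK_RS03825	-	MCHK_RS03830	-	866178	866302	125	RF00050; FMN	no	
MH_s9	-	1019673	1019854	182	IGR_G-732	MCHK_RS04550	+	MCHK_RS04555	+	no	no	no	RF00174, Cobalamin, riboswitch	no	
MH_s10	+	1235498	1235640	143	IGR_G-893	MCHK_RS05520	-	MCHK_RS05525	+	1235474	1235614	141	un	yes	
MH_s11	+	1431996	1432205	210	IGR_G-1069	MCHK_RS06525	+	MCHK_RS06530	-	1432008	1432172	165	un	yes	
MH_s12	+	1559635	1559846	212	IGR_G-1203	MCHK_RS07310	+	MCHK_RS07315	+	1559651	1559735	85	un	no	
MH_s13	+	2052016	2052131	116	IGR_G-1629	MCHK_RS09840	-	MCHK_RS09845	+	2051956	2052321	366	un	no	2052083-2052213/+ (131)
MH_s14	+	2507050	2507158	109	IGR_G-2003	MCHK_RS12070	-	MCHK_RS12075	+	2506941	2507200	260	RF00504, glycine riboswitch	no	
MH_s15	-	2726638	2726908	271	IGR_G-2184	MCHK_RS13135	-	MCHK_RS13140	-	2726658	2726861	204	un	yes	
MH_s16	-	2796896	2797053	158	IGR_G-2240	MCHK_RS13460	+	MCHK_RS13465	-	2796947	2797069	123	un	no	
MH_s17	-	2884712	2884910	199	IGR_G-2307	MCHK_RS13870	-	MCHK_RS13875	+	no	no	no	RF00174, Cobalamin, riboswitch	no	
MH_s18	+	2932002	2932224	223	IGR_G-2341	MCHK_RS14095	+	MCHK_RS14100	+	2931996	2932217	222	Cobalamin(maybe)	no	
MH_s19	-	3053514	3053641	128	IGR_G-2430	MCHK_RS14720	-	MCHK_RS14725	+	3053513	3053602	90	RF01849, alpha_tmRNA	no	
MH_s20	-	3136500	3136900	401	IGR_G-2487	MCHK_RS15095	-	MCHK_RS15100	-	3136500	3136902	403	RF00010, RNaseP	no	
MH_s21	-	3299281	3299382	102	IGR_G-2605	MCHK_RS15825	-	MCHK_RS15830	+	no	no	no	RF0059, TPP riboswitch	no	
MH_s22	+	3491673	3491835	163	IGR_G-2770	MCHK_RS16785	+	MCHK_RS16795	-	3491690	3491875	186	un	yes	
MH_s23	-	4347901	4348213	313	IGR_G-3495	MCHK_RS21045	-	MCHK_RS21050	+	4347914	4348238	325	RF00518, speF	no	
MH_s24	+	4403151	4403231	81	IGR_G-3535	MCHK_RS21275	-	MCHK_RS21280	-	4403128	4403198	71	RF00519, suhB	no	
MH_s25	-	4532142	4532343	202	IGR_G-3642	MCHK_RS21925	+	MCHK_RS21930	+	4532144	4532330	187	un	yes	4531972-4532239/- (268)
MH_s26	-	4579379	4579594	216	IGR_G-3682	MCHK_RS22185	-	MCHK_RS22190	+	4579346	4579554	209	un	no	
MH_s27	+	4677352	4677482	131	IGR_G-3753	MCHK_RS22640	-	MCHK_RS22645	-	4677314	4677396	83	RF01118, snmRNA	no	
MH_s28	-	4681680	4681810	131	IGR_G-3754	MCHK_RS22655	-	MCHK_RS22660	-	4681648	4681722	75	n3555, AJ544053, snmRNA	no	
MH_s29	+	4780322	4780399	78	IGR_G-3840	MCHK_RS23145	-	MCHK_RS23150	+	4780323	4780503	181	RF00521, SAM_alpha	no	
MH_s30	-	5045563	5045615	53	IGR_G-4067	MCHK_RS24485	-	MCHK_RS24490	-	5045561	5045692	132	RF00517, SerC	no	
MH_s31	-	5068059	5068203	145	IGR_G-4090	MCHK_RS24605	-	MCHK_RS24610	-	5068057	5068160	104	un	no	
MH_s32	-	5092499	5092668	170	IGR_G-4120	MCHK_RS24760	-	MCHK_RS24765	+	5092499	5092638	140	RF00013, 6S RNA	no	
MH_s33	-	5178956	5179352	397	IGR_G-4190	MCHK_RS25165	-	MCHK_RS25170	-	5178945	5179159	215	RF01867, CC2171	no	
MH_s34	-	5355054	5355121	68	IGR_G-4348	MCHK_RS26065	-	MCHK_RS26070	-	5355042	5355141	100	RF00520, ybhL	no	
MH_s35	+	5723839	5723889	51	IGR_G-4638	MCHK_RS27895	-	MCHK_RS27900	+	5723811	5723946	135	RF01068, mini-ykkC	no	
MH_s36	-	5779014	5779103	90	IGR_G-4677	MCHK_RS28170	-	MCHK_RS28175	-	5779015	5779087	73	un	yes	
MH_s37	-	5845302	5845459	158	IGR_G-4735	MCHK_RS28500	-	MCHK_RS28505	-	5845359	5845423	65	un	no	
MH_s38	+	5936318	5936708	391	IGR_G-4809	MCHK_RS28940	-	MCHK_RS28945	+	no	no	no	RF00174, Cobalamin_riboswitch	no	
MH_s39	+	6026827	6027187	361	IGR_G-4878	MCHK_RS29340	-	MCHK_RS29345	-	6026852	6027101	250	un	yes	
MH_s40	+	6301829	6302173	345	IGR_G-5080	MCHK_RS30580	-	MCHK_RS30585	+	6301885	6302173	289	RF00169, Bacteria small SRP, 4.5S	no	
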