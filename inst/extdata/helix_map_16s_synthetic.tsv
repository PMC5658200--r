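molecule	helix	strand5_start	strand5_end	strand3_start	strand3_end
16S	H6	40	49	58	67
16S	H9	160	169	178	187
16S	H10	280	289	298	307
16S	H15	400	409	418	427
16S	H18	520	529	538	547
16S	H21	640	649	658	667
16S	H24	760	769	778	787
16S	H27	880	889	898	907
16S	H28	1000	1009	1018	1027
16S	H33	1120	1129	1138	1147
16S	H38	1240	1249	1258	1267
16S	H42	1360	1369	1378	1387
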