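lg	bins	physLoci	physKb	mappedLoci	mapCm
A1	60	2672	27105	913	75.9
A2	74	2425	29627	946	98.2
A3	94	3185	35753	1330	114.3
A4	50	2112	21080	1085	57.6
A5	78	2332	25706	1121	99.6
A6	89	2302	26146	1019	100.1
A7	46	2529	25458	1333	60
A8	55	1863	21685	953	85
A9	89	2452	40546	1279	127.5
A10	63	2053	17911	841	75.6
C1	46	3418	45604	1882	71.3
C2	47	3743	47311	1241	69.8
C3	118	3870	67777	1804	165.3
C4	88	4399	55069	1443	136.9
C5	65	1600	48717	651	124.4
C6	40	1982	40797	980	42.6
C7	82	2784	48823	1360	101.7
C8	68	2151	44716	742	104
C9	58	1782	55995	843	106
Total	1310	49744	725833	21766	1814.9
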