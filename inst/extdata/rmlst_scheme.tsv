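locus	min_len	max_len
rpsB	369	1479
rpsC	339	1359
rpsD	306	1221
rpsE	249	999
rpsF	165	660
rpsG	234	939
rpsH	201	801
rpsI	195	780
rpsJ	156	621
rpsK	195	780
rpsL	186	741
rpsM	180	720
rpsN	141	561
rpsO	135	540
rpsP	126	501
rpsQ	129	519
rpsR	114	459
rpsS	141	561
rpsT	129	519
rpsU	105	420
rplA	345	1380
rplB	414	1659
rplC	315	1260
rplD	309	1239
rplE	270	1080
rplF	264	1059
rplI	225	900
rplJ	249	999
rplK	216	861
rplL	183	729
rplM	216	861
rplN	186	741
rplO	216	861
rplP	204	819
rplQ	189	759
rplR	174	699
rplS	174	699
rplT	177	711
rplU	156	621
rplV	165	660
rplW	150	600
rplX	156	621
rplY	144	570
rpmA	129	519
rpmB	117	471
rpmC	96	381
rpmD	90	360
rpmE	108	429
rpmF	90	360
rpmG	84	339
rpmH	66	270
rpmI	96	390
rpmJ	60	231
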