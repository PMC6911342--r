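pre_mirna	similarity_len	evalue	leaf_contig	leaf_len	leaf_ac	leaf_lc	phloem_contig	phloem_len	phloem_ac	phloem_lc
miR156b	45	1E-15	L16156	1300	108.4	268	NA	NA	NA	NA
miR156c	103	3E-40	L1898	3420	23.1	73	NA	NA	NA	NA
miR156e	93	2E-23	L16749	1261	11.2	48	NA	NA	NA	NA
miR156i	121	4E-22	L20685	1010	8.3	31	NA	NA	NA	NA
miR159a	209	2E-65	L24286	804	14.7	23	P21134	784	72.9	148
miR166d	120	1E-25	L28720	589	1.8	4	P19669	841	98.0	162
miR166e	287	3E-32	L23584	842	7.2	19	P31502	479	20.7	41
miR167b	98	7E-35	L25833	721	23.9	52	NA	NA	NA	NA
miR167e	107	9E-22	L25150	758	74.8	275	NA	NA	NA	NA
miR168	218	2E-52	L23344	856	12.5	46	P7902	1508	10.9	56
miR169f	102	3E-26	L31431	494	28.8	82	NA	NA	NA	NA
miR171i1	187	8E-43	L9649	1849	6.0	11	P3867	1986	48.0	133
miR171i2	192	2E-26	L8895	1930	24.7	31	P5314	1784	11.3	23
miR319a	188	2E-70	NA	NA	NA	NA	P20012	828	42.9	53
miR319d	192	1E-53	NA	NA	NA	NA	P20793	797	20.8	36
miR390a	116	5E-24	NA	NA	NA	NA	P37982	364	26.7	111
miR390b	135	3E-21	NA	NA	NA	NA	P38121	362	18.9	49
miR393a	113	9E-28	L11031	1718	80.8	5	P10713	1292	102.9	1042
miR396b1	149	5E-32	L19994	1055	16.8	50	P29987	513	22.8	61
miR396b2	150	2E-18	L21853	939	14.7	66	NA	NA	NA	NA
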