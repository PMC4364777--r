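gene	group	brain_xi	brain_xa	brain_rpkm	spleen_xi	spleen_xa	spleen_rpkm	ovary_xi	ovary_xa	ovary_rpkm	human_escape	count_scope
Ddx3x	group1	56	178	85	76	215	120	66	216	120	9/9	exonic
Kdm6a	group1	6	18	10	25	39	28	13	28	17	9/9	exonic
Eif2s3x	group1	130	356	65	267	588	109	133	379	77	9/9	exonic
Xist	group1	1755	4	50	2832	7	89	1849	7	60	9/9	exonic
5530601H04Rik	group1	8	28	3	7	37	5	10	24	3	-	exonic
Pbdc1	group1	2	20	6	7	30	17	10	26	11	0/9	exonic
Kdm5c	group1	19	64	10	43	120	23	32	91	18	9/9	exonic
Cybb	group1	0	3	0	14	607	55	2	31	3	-	exonic
Utp14a	group1	2	31	9	5	119	35	4	47	15	3/9	exonic
Ftx	group1	9	115	12	4	87	10	4	34	4	-	exonic
Firre	group1	2	208	11	6	74	4	5	495	29	-	exonic+intronic
Slc16a2	group1	2	39	7	2	11	2	3	38	8	0/5	exonic
Plp1	group2	13	4561	901	0	7	2	0	25	6	1/9	exonic
Gpm6b	group2	35	2557	334	0	81	12	0	101	16	9/9	exonic
Syp	group2	10	1662	358	0	7	2	0	8	2	2/9	exonic
Gdi1	group2	4	439	144	1	141	53	1	135	47	-	exonic
Gprasp1	group2	3	1775	136	0	86	8	2	363	32	-	exonic
Tmem47	group2	5	320	45	0	18	3	1	121	20	0/9	exonic
Cfp	group2	0	12	6	12	210	131	1	18	11	0/9	exonic
Bgn	group2	1	14	5	5	332	91	1	218	69	0/6	exonic
Vsig4	group2	0	0	0	2	3	2	0	1	0	-	exonic
5730416F02Rik	group2	0	0	0	6	3	6	2	1	3	-	exonic
5430427O19Rik	group2	0	1	0	4	79	9	1	5	0	-	exonic
Lamp2	group2	0	168	43	0	318	79	3	709	183	0/9	exonic
AU015836	group2	0	0	0	0	0	0	4	6	3	-	exonic
Kif4	group2	0	3	0	0	182	21	2	34	5	0/4	exonic
Rlim	group2	1	187	13	1	282	23	2	209	19	0/9	exonic
Sh3bgrl	group2	0	290	46	1	402	71	3	847	148	8/9	exonic
Fam199x	group2	0	65	4	0	35	2	2	57	4	0/9	exonic
Tmem164	group2	0	87	7	2	154	14	3	229	21	-	exonic
Alg13	group2	0	15	4	0	17	5	2	29	8	5/9	exonic
Tmem29	group2	1	24	16	1	16	13	2	18	17	0/5	exonic
Pdha1	group2	2	575	106	1	264	57	2	725	157	0/6	exonic
AU022751	group2	0	0	0	0	0	0	11	11	6	-	exonic
Rnf128	group2	0	33	8	0	3	1	9	262	79	-	exonic
Car5b	group2	0	9	1	0	6	1	10	281	42	9/9	exonic
Bmp15	group2	0	0	0	0	0	0	25	24	8	-	exonic
Flna	group2	0	76	10	1	616	82	5	859	120	0/9	exonic
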