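accession	species	whole_length	whole_at	pcg_length	pcg_at	rrnl_length	rrnl_at	rrns_length	rrns_at	pcg_t	pcg_c	pcg_a	pcg_g	at_skew	gc_skew
KJ713152	Allantus luctifer	15418	81.13	11212	79.90	1340	84.10	807	83.52	45.0	10.2	34.9	10.0	-0.126	-0.010
KR703582	Asiemphytus rufocephalus	14864	81.40	11257	80.30	1339	85.06	803	83.44	45.1	9.7	35.2	10.0	-0.123	0.015
JX566509	Monocellicampa pruni	15169	77.22	11176	75.20	1356	82.67	797	81.18	42.2	12.9	33.0	11.9	-0.122	-0.040
KR703581	Tenthredo tienmushana	14942	80.14	11278	79.00	1355	83.17	797	83.69	44.6	10.6	34.4	10.4	-0.129	-0.010
KT921411	Trichiosoma anthracinum	15392	80.76	11185	79.30	1351	84.46	800	83.50	44.1	10.4	35.2	10.3	-0.112	-0.005
AY787816	Perga condei	13413	77.92	10148	76.50	1357	83.05	728	80.91	43.2	11.6	33.3	12.0	-0.129	0.017
FJ478173	Cephus cinctus	19337	81.96	11291	79.10	1386	84.63	1011	80.51	44.0	10.7	35.1	10.2	-0.113	-0.024
KM377623	Cephus pygmeus	16145	79.82	11293	77.50	1367	84.56	1008	84.42	43.2	11.1	34.3	11.3	-0.115	0.009
KM377624	Cephus sareptanus	15212	79.20	11285	77.30	1379	83.76	1014	85.21	42.8	11.6	34.5	11.1	-0.107	-0.022
FJ478174	Orussus occidentalis	15947	76.21	11174	74.20	1336	80.09	787	81.07	42.0	13.7	32.2	12.1	-0.132	-0.062
KP163643	Apis mellifera	15427	84.18	11029	83.20	1366	84.55	781	81.31	46.1	8.6	37.1	8.3	-0.108	-0.018
KJ735511	Vespa bicolor	16937	81.72	11230	79.30	1451	84.77	838	85.20	44.3	11.1	35.0	9.6	-0.117	-0.072
EU871947	Diadegma semiclausum	18728	87.41	11122	83.70	1392	88.00	768	88.54	47.0	8.2	36.7	8.1	-0.123	-0.006
DQ302100	Vanhornia eucnemidarum	16567	80.14	11068	78.20	1327	82.82	395	80.76	42.7	11.7	35.5	10.0	-0.092	-0.078
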