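locus	index_variant	cytoband	pos	trait	stratum	n_independent	ea	oa	eaf	beta	se	p	var_explained_pct	p_interaction	candidate_genes
1	rs139036121	Xp22.31	8912628	eGFR	male	1	T	C	0.27	-0.0032	0.00037	1.0e-17	0.024	2.0e-7	FAM9B
2	rs5909184	Xp22.13	18482665	eGFR	overall	1	T	C	0.34	0.0027	0.00028	4.9e-22	0.013	0.36	CDKL5
3	rs72616719	Xp11.23	47166532	eGFR	overall	1	A	G	0.58	-0.0015	0.00026	9.9e-9	0.0044	0.59	CDK16,USP11
4	rs189618857	Xq12	66156010	eGFR	male	1	A	T	0.83	0.003	0.00055	3.8e-8	0.013	1.5e-3	AR,EDA2R
5	rs2063579	Xq21.1	79925246	eGFR	overall	1	G	A	0.70	-0.0015	0.00028	4.3e-8	0.0039	0.14	BRWD3
6	rs1802288	Xq22.1	99890204	eGFR	overall	1	T	C	0.17	-0.0028	0.00038	8.7e-13	0.0084	0.065	TSPAN6
7A	rs3850318	Xq22.1	100938892	eGFR	overall	1	C	G	0.62	-0.002	0.00031	7.0e-11	0.0057	0.85	ARMCX2,ARMCX4
7B	rs149995096	Xq22.1	100479327	eGFR	female	1	T	C	0.18	-0.0031	0.00052	2.2e-9	0.0093	5.1e-4	DRP2
8	rs11092455	Xq22.2	102925716	eGFR	overall	1	T	C	0.44	0.0016	0.00027	4.5e-9	0.0052	0.26	MORF4L2,TCEAL3
9	rs181497961	Xq22.3	106168067	eGFR	overall	2	A	G	0.023	-0.012	0.00099	1.4e-35	0.026	0.81	CLDN2
10	rs5942852	Xq23	109094393	eGFR	overall	1	C	T	0.76	-0.002	0.00031	3.0e-11	0.0058	0.42	ACSL4
11	rs16275	Xq24	118582383	eGFR	overall	1	G	A	0.68	-0.0016	0.00027	2.6e-9	0.0046	0.73	SLC25A5
12	rs5931180	Xq25	125656689	eGFR	overall	1	A	T	0.37	-0.0021	0.00026	9.8e-16	0.0084	0.38	DCAF12L1
13	rs5933079	Xq26.2	131251326	eGFR	overall	1	T	C	0.26	0.0022	0.0003	1.7e-13	0.0071	0.025	MST4
14	rs5933443	Xq26.3	133797249	eGFR	overall	1	A	T	0.68	0.0029	0.0003	1.7e-22	0.013	0.047	HPRT1
15	chr23:152898260	Xq28	152898260	eGFR	overall	1	A	C	0.54	-0.0026	0.00027	7.9e-23	0.013	0.97	DUSP9,FAM58A
16	rs6625094	Xq12	66301811	UA	overall	1	T	G	0.82	-0.024	0.0033	3.8e-13	0.01	0.13	AR,EDA2R
17	rs34687188	Xq13.1	71509443	UA	overall	1	AT	A	0.72	0.017	0.0028	2.6e-9	0.0069	0.6	CITED1,PIN4
18	rs34884874	Xq22.1	100885798	UA	overall	1	CT	C	0.75	0.023	0.0027	6.2e-17	0.014	0.36	ARMCX2,ARMCX4
19	rs34815154	Xq22.1	102552032	UA	overall	1	A	AT	0.37	-0.014	0.0024	1.7e-8	0.0062	0.34	MORF4L2,TCEAL3
20	rs112708523	Xq25	125602218	UA	overall	1	A	AT	0.40	-0.018	0.0024	3.0e-14	0.011	0.034	DCAF12L1
21	rs202138804	Xq26.3	133799101	UA	overall	2	A	AGT	0.76	-0.016	0.0027	5.2e-9	0.0066	0.86	HPRT1
22	rs4328011	Xq28	152898261	UA	overall	2	A	G	0.55	0.009	0.001	2.0e-17	0.011	0.15	DUSP9,FAM58A
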