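# Synthetic backbone N-H RDC set, Pf1-style weak alignment (115 records).
# Generated from the packaged 115-residue hinge template (hinge_topology(80, 25, 10),
# bend 120 deg) under the Saupe tensor (sxx, syy, sxy, sxz, syz) =
# (4e-4, -2e-4, 1e-4, 3e-4, -2.5e-4), d_max = 21700 Hz, Gaussian noise sd 0.5 Hz, seed 115.
# Columns: residue atom_a atom_b value_hz error_hz medium
1	N	H	-1.310112	0.500000	Pf1-synthetic
2	N	H	-3.791045	0.500000	Pf1-synthetic
3	N	H	6.325773	0.500000	Pf1-synthetic
4	N	H	7.986002	0.500000	Pf1-synthetic
5	N	H	2.793988	0.500000	Pf1-synthetic
6	N	H	-3.299134	0.500000	Pf1-synthetic
7	N	H	10.133761	0.500000	Pf1-synthetic
8	N	H	6.215995	0.500000	Pf1-synthetic
9	N	H	-2.031424	0.500000	Pf1-synthetic
10	N	H	2.247039	0.500000	Pf1-synthetic
11	N	H	9.256805	0.500000	Pf1-synthetic
12	N	H	4.616060	0.500000	Pf1-synthetic
13	N	H	-5.057123	0.500000	Pf1-synthetic
14	N	H	8.475282	0.500000	Pf1-synthetic
15	N	H	7.030850	0.500000	Pf1-synthetic
16	N	H	0.588814	0.500000	Pf1-synthetic
17	N	H	-0.251682	0.500000	Pf1-synthetic
18	N	H	9.735891	0.500000	Pf1-synthetic
19	N	H	5.793900	0.500000	Pf1-synthetic
20	N	H	-3.564827	0.500000	Pf1-synthetic
21	N	H	5.563740	0.500000	Pf1-synthetic
22	N	H	7.792464	0.500000	Pf1-synthetic
23	N	H	2.971886	0.500000	Pf1-synthetic
24	N	H	-3.302034	0.500000	Pf1-synthetic
25	N	H	10.045476	0.500000	Pf1-synthetic
26	N	H	6.767238	0.500000	Pf1-synthetic
27	N	H	-2.119009	0.500000	Pf1-synthetic
28	N	H	2.626089	0.500000	Pf1-synthetic
29	N	H	9.857316	0.500000	Pf1-synthetic
30	N	H	3.714499	0.500000	Pf1-synthetic
31	N	H	-5.012772	0.500000	Pf1-synthetic
32	N	H	8.574393	0.500000	Pf1-synthetic
33	N	H	6.482255	0.500000	Pf1-synthetic
34	N	H	0.853858	0.500000	Pf1-synthetic
35	N	H	-0.859926	0.500000	Pf1-synthetic
36	N	H	9.748926	0.500000	Pf1-synthetic
37	N	H	5.627872	0.500000	Pf1-synthetic
38	N	H	-4.019154	0.500000	Pf1-synthetic
39	N	H	5.668247	0.500000	Pf1-synthetic
40	N	H	8.601476	0.500000	Pf1-synthetic
41	N	H	3.607371	0.500000	Pf1-synthetic
42	N	H	-4.091980	0.500000	Pf1-synthetic
43	N	H	9.919401	0.500000	Pf1-synthetic
44	N	H	5.339854	0.500000	Pf1-synthetic
45	N	H	-3.145134	0.500000	Pf1-synthetic
46	N	H	2.078458	0.500000	Pf1-synthetic
47	N	H	8.580175	0.500000	Pf1-synthetic
48	N	H	5.807069	0.500000	Pf1-synthetic
49	N	H	-5.220756	0.500000	Pf1-synthetic
50	N	H	8.618725	0.500000	Pf1-synthetic
51	N	H	8.100564	0.500000	Pf1-synthetic
52	N	H	0.510202	0.500000	Pf1-synthetic
53	N	H	-0.490463	0.500000	Pf1-synthetic
54	N	H	10.735880	0.500000	Pf1-synthetic
55	N	H	5.157798	0.500000	Pf1-synthetic
56	N	H	-4.582703	0.500000	Pf1-synthetic
57	N	H	6.410058	0.500000	Pf1-synthetic
58	N	H	7.482593	0.500000	Pf1-synthetic
59	N	H	2.976721	0.500000	Pf1-synthetic
60	N	H	-3.173133	0.500000	Pf1-synthetic
61	N	H	10.982389	0.500000	Pf1-synthetic
62	N	H	5.812152	0.500000	Pf1-synthetic
63	N	H	-1.417025	0.500000	Pf1-synthetic
64	N	H	2.405406	0.500000	Pf1-synthetic
65	N	H	9.546296	0.500000	Pf1-synthetic
66	N	H	5.045465	0.500000	Pf1-synthetic
67	N	H	-4.828694	0.500000	Pf1-synthetic
68	N	H	8.076602	0.500000	Pf1-synthetic
69	N	H	6.198022	0.500000	Pf1-synthetic
70	N	H	0.224800	0.500000	Pf1-synthetic
71	N	H	-1.229787	0.500000	Pf1-synthetic
72	N	H	9.747270	0.500000	Pf1-synthetic
73	N	H	5.525595	0.500000	Pf1-synthetic
74	N	H	-4.521046	0.500000	Pf1-synthetic
75	N	H	5.240318	0.500000	Pf1-synthetic
76	N	H	7.605519	0.500000	Pf1-synthetic
77	N	H	3.261949	0.500000	Pf1-synthetic
78	N	H	-3.711364	0.500000	Pf1-synthetic
79	N	H	9.453371	0.500000	Pf1-synthetic
80	N	H	-2.896752	0.500000	Pf1-synthetic
81	N	H	-10.243647	0.500000	Pf1-synthetic
82	N	H	0.538403	0.500000	Pf1-synthetic
83	N	H	0.142066	0.500000	Pf1-synthetic
84	N	H	0.462291	0.500000	Pf1-synthetic
85	N	H	0.643605	0.500000	Pf1-synthetic
86	N	H	-0.796789	0.500000	Pf1-synthetic
87	N	H	0.620595	0.500000	Pf1-synthetic
88	N	H	0.819427	0.500000	Pf1-synthetic
89	N	H	1.471574	0.500000	Pf1-synthetic
90	N	H	0.547711	0.500000	Pf1-synthetic
91	N	H	-0.264282	0.500000	Pf1-synthetic
92	N	H	8.054014	0.500000	Pf1-synthetic
93	N	H	-10.836285	0.500000	Pf1-synthetic
94	N	H	9.550111	0.500000	Pf1-synthetic
95	N	H	-0.259876	0.500000	Pf1-synthetic
96	N	H	1.066438	0.500000	Pf1-synthetic
97	N	H	-2.766148	0.500000	Pf1-synthetic
98	N	H	3.390072	0.500000	Pf1-synthetic
99	N	H	7.008400	0.500000	Pf1-synthetic
100	N	H	-9.426197	0.500000	Pf1-synthetic
101	N	H	7.031869	0.500000	Pf1-synthetic
102	N	H	-1.865254	0.500000	Pf1-synthetic
103	N	H	5.893265	0.500000	Pf1-synthetic
104	N	H	-8.742421	0.500000	Pf1-synthetic
105	N	H	8.228525	0.500000	Pf1-synthetic
106	N	H	2.610849	0.500000	Pf1-synthetic
107	N	H	-4.966947	0.500000	Pf1-synthetic
108	N	H	3.498981	0.500000	Pf1-synthetic
109	N	H	-0.606299	0.500000	Pf1-synthetic
110	N	H	7.498241	0.500000	Pf1-synthetic
111	N	H	-11.081556	0.500000	Pf1-synthetic
112	N	H	9.360106	0.500000	Pf1-synthetic
113	N	H	-1.273871	0.500000	Pf1-synthetic
114	N	H	0.727142	0.500000	Pf1-synthetic
115	N	H	2.254492	0.500000	Pf1-synthetic
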