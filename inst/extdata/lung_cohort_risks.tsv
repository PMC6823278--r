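subject_id	absolute_risk	relative_risk	stratum
17	0.283	5.0	men
23	0.174	3.1	men
27	0.174	3.1	men
25	0.152	2.7	men
26	0.145	2.6	men
16	0.141	2.5	men
2	0.138	2.5	men
32	0.122	2.2	men
22	0.119	2.1	men
24	0.119	2.1	men
19	0.094	1.7	men
4	0.092	1.6	men
10	0.092	1.6	men
11	0.092	1.6	men
30	0.087	1.5	men
28	0.086	3.4	women
15	0.084	1.5	men
43	0.081	1.4	men
18	0.081	3.2	women
33	0.078	1.4	men
8	0.077	1.4	men
31	0.077	3.0	women
9	0.076	1.3	men
34	0.073	1.3	men
1	0.072	1.3	men
47	0.072	1.3	men
38	0.071	1.3	men
21	0.069	2.7	women
14	0.067	2.6	women
48	0.064	1.1	men
40	0.063	1.1	men
12	0.061	1.1	men
29	0.058	2.3	women
42	0.056	1.0	men
20	0.054	1.0	men
39	0.053	0.9	men
37	0.044	0.8	men
6	0.042	0.8	men
3	0.040	0.7	men
41	0.040	0.7	men
44	0.040	0.7	men
46	0.040	1.6	women
35	0.038	0.7	men
7	0.035	0.6	men
45	0.035	0.6	men
5	0.035	1.4	women
13	0.022	0.8	women
36	0.019	0.7	women
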