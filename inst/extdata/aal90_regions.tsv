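index	name	abbreviation	hemisphere
1	Precentral gyrus	PreCG.L	L
2	Precentral gyrus	PreCG.R	R
3	Superior frontal gyrus (dorsolateral)	SFGdor.L	L
4	Superior frontal gyrus (dorsolateral)	SFGdor.R	R
5	Superior frontal gyrus (orbital)	ORBsup.L	L
6	Superior frontal gyrus (orbital)	ORBsup.R	R
7	Middle frontal gyrus	MFG.L	L
8	Middle frontal gyrus	MFG.R	R
9	Middle frontal gyrus (orbital)	ORBmid.L	L
10	Middle frontal gyrus (orbital)	ORBmid.R	R
11	Inferior frontal gyrus (opercular)	IFGoperc.L	L
12	Inferior frontal gyrus (opercular)	IFGoperc.R	R
13	Inferior frontal gyrus (triangular)	IFGtriang.L	L
14	Inferior frontal gyrus (triangular)	IFGtriang.R	R
15	Inferior frontal gyrus (orbital)	ORBinf.L	L
16	Inferior frontal gyrus (orbital)	ORBinf.R	R
17	Rolandic operculum	ROL.L	L
18	Rolandic operculum	ROL.R	R
19	Supplementary motor area	SMA.L	L
20	Supplementary motor area	SMA.R	R
21	Olfactory cortex	OLF.L	L
22	Olfactory cortex	OLF.R	R
23	Superior frontal gyrus (medial)	SFGmed.L	L
24	Superior frontal gyrus (medial)	SFGmed.R	R
25	Superior frontal gyrus (medial orbital)	ORBsupmed.L	L
26	Superior frontal gyrus (medial orbital)	ORBsupmed.R	R
27	Gyrus rectus	REC.L	L
28	Gyrus rectus	REC.R	R
29	Insula	INS.L	L
30	Insula	INS.R	R
31	Anterior cingulate gyrus	ACG.L	L
32	Anterior cingulate gyrus	ACG.R	R
33	Median cingulate gyrus	DCG.L	L
34	Median cingulate gyrus	DCG.R	R
35	Posterior cingulate gyrus	PCG.L	L
36	Posterior cingulate gyrus	PCG.R	R
37	Hippocampus	HIP.L	L
38	Hippocampus	HIP.R	R
39	Parahippocampal gyrus	PHG.L	L
40	Parahippocampal gyrus	PHG.R	R
41	Amygdala	AMYG.L	L
42	Amygdala	AMYG.R	R
43	Calcarine cortex	CAL.L	L
44	Calcarine cortex	CAL.R	R
45	Cuneus	CUN.L	L
46	Cuneus	CUN.R	R
47	Lingual gyrus	LING.L	L
48	Lingual gyrus	LING.R	R
49	Superior occipital gyrus	SOG.L	L
50	Superior occipital gyrus	SOG.R	R
51	Middle occipital gyrus	MOG.L	L
52	Middle occipital gyrus	MOG.R	R
53	Inferior occipital gyrus	IOG.L	L
54	Inferior occipital gyrus	IOG.R	R
55	Fusiform gyrus	FFG.L	L
56	Fusiform gyrus	FFG.R	R
57	Postcentral gyrus	PoCG.L	L
58	Postcentral gyrus	PoCG.R	R
59	Superior parietal gyrus	SPG.L	L
60	Superior parietal gyrus	SPG.R	R
61	Inferior parietal lobule	IPL.L	L
62	Inferior parietal lobule	IPL.R	R
63	Supramarginal gyrus	SMG.L	L
64	Supramarginal gyrus	SMG.R	R
65	Angular gyrus	ANG.L	L
66	Angular gyrus	ANG.R	R
67	Precuneus	PCUN.L	L
68	Precuneus	PCUN.R	R
69	Paracentral lobule	PCL.L	L
70	Paracentral lobule	PCL.R	R
71	Caudate nucleus	CAU.L	L
72	Caudate nucleus	CAU.R	R
73	Putamen	PUT.L	L
74	Putamen	PUT.R	R
75	Pallidum	PAL.L	L
76	Pallidum	PAL.R	R
77	Thalamus	THA.L	L
78	Thalamus	THA.R	R
79	Heschl gyrus	HES.L	L
80	Heschl gyrus	HES.R	R
81	Superior temporal gyrus	STG.L	L
82	Superior temporal gyrus	STG.R	R
83	Temporal pole (superior)	TPOsup.L	L
84	Temporal pole (superior)	TPOsup.R	R
85	Middle temporal gyrus	MTG.L	L
86	Middle temporal gyrus	MTG.R	R
87	Temporal pole (middle)	TPOmid.L	L
88	Temporal pole (middle)	TPOmid.R	R
89	Inferior temporal gyrus	ITG.L	L
90	Inferior temporal gyrus	ITG.R	R
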