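region_index	region_name	label	hemisphere
1	Parcel_DefaultA_1	DefaultA	left
2	Parcel_DefaultA_2	DefaultA	right
3	Parcel_DefaultA_3	DefaultA	left
4	Parcel_DefaultA_4	DefaultA	right
5	Parcel_DefaultA_5	DefaultA	left
6	Parcel_DefaultB_6	DefaultB	right
7	Parcel_DefaultB_7	DefaultB	left
8	Parcel_DefaultB_8	DefaultB	right
9	Parcel_DefaultB_9	DefaultB	left
10	Parcel_DefaultB_10	DefaultB	right
11	Parcel_DefaultC_11	DefaultC	left
12	Parcel_DefaultC_12	DefaultC	right
13	Parcel_DefaultC_13	DefaultC	left
14	Parcel_DefaultC_14	DefaultC	right
15	Parcel_DefaultC_15	DefaultC	left
16	Parcel_ContA_16	ContA	right
17	Parcel_ContA_17	ContA	left
18	Parcel_ContA_18	ContA	right
19	Parcel_ContA_19	ContA	left
20	Parcel_ContA_20	ContA	right
21	Parcel_ContB_21	ContB	left
22	Parcel_ContB_22	ContB	right
23	Parcel_ContB_23	ContB	left
24	Parcel_ContB_24	ContB	right
25	Parcel_ContB_25	ContB	left
26	Parcel_ContC_26	ContC	right
27	Parcel_ContC_27	ContC	left
28	Parcel_ContC_28	ContC	right
29	Parcel_ContC_29	ContC	left
30	Parcel_ContC_30	ContC	right
31	Parcel_SalVentAttnA_31	SalVentAttnA	left
32	Parcel_SalVentAttnA_32	SalVentAttnA	right
33	Parcel_SalVentAttnA_33	SalVentAttnA	left
34	Parcel_SalVentAttnA_34	SalVentAttnA	right
35	Parcel_SalVentAttnA_35	SalVentAttnA	left
36	Parcel_SalVentAttnB_36	SalVentAttnB	right
37	Parcel_SalVentAttnB_37	SalVentAttnB	left
38	Parcel_SalVentAttnB_38	SalVentAttnB	right
39	Parcel_SalVentAttnB_39	SalVentAttnB	left
40	Parcel_SalVentAttnB_40	SalVentAttnB	right
41	Parcel_DorsAttnA_41	DorsAttnA	left
42	Parcel_DorsAttnA_42	DorsAttnA	right
43	Parcel_DorsAttnA_43	DorsAttnA	left
44	Parcel_DorsAttnA_44	DorsAttnA	right
45	Parcel_DorsAttnA_45	DorsAttnA	left
46	Parcel_DorsAttnB_46	DorsAttnB	right
47	Parcel_DorsAttnB_47	DorsAttnB	left
48	Parcel_DorsAttnB_48	DorsAttnB	right
49	Parcel_DorsAttnB_49	DorsAttnB	left
50	Parcel_DorsAttnB_50	DorsAttnB	right
51	Parcel_LimbicA_51	LimbicA	left
52	Parcel_LimbicA_52	LimbicA	right
53	Parcel_LimbicA_53	LimbicA	left
54	Parcel_LimbicA_54	LimbicA	right
55	Parcel_LimbicA_55	LimbicA	left
56	Parcel_LimbicB_56	LimbicB	right
57	Parcel_LimbicB_57	LimbicB	left
58	Parcel_LimbicB_58	LimbicB	right
59	Parcel_LimbicB_59	LimbicB	left
60	Parcel_LimbicB_60	LimbicB	right
61	Parcel_SomMotA_61	SomMotA	left
62	Parcel_SomMotA_62	SomMotA	right
63	Parcel_SomMotA_63	SomMotA	left
64	Parcel_SomMotA_64	SomMotA	right
65	Parcel_SomMotA_65	SomMotA	left
66	Parcel_SomMotB_66	SomMotB	right
67	Parcel_SomMotB_67	SomMotB	left
68	Parcel_SomMotB_68	SomMotB	right
69	Parcel_SomMotB_69	SomMotB	left
70	Parcel_VisCent_70	VisCent	right
71	Parcel_VisCent_71	VisCent	left
72	Parcel_VisCent_72	VisCent	right
73	Parcel_VisCent_73	VisCent	left
74	Parcel_VisPeri_74	VisPeri	right
75	Parcel_VisPeri_75	VisPeri	left
76	Parcel_VisPeri_76	VisPeri	right
77	Parcel_VisPeri_77	VisPeri	left
78	Parcel_TempPar_78	TempPar	right
79	Parcel_TempPar_79	TempPar	left
80	Parcel_TempPar_80	TempPar	right
81	Parcel_TempPar_81	TempPar	left
82	ROI_Accumbens-L_82	Accumbens-L	left
83	ROI_Accumbens-R_83	Accumbens-R	right
84	ROI_Amygdala-L_84	Amygdala-L	left
85	ROI_Amygdala-R_85	Amygdala-R	right
86	ROI_Caudate-L_86	Caudate-L	left
87	ROI_Caudate-R_87	Caudate-R	right
88	ROI_Cerebellum-L_88	Cerebellum-L	left
89	ROI_Cerebellum-R_89	Cerebellum-R	right
90	ROI_Diencephalon-L_90	Diencephalon-L	left
91	ROI_Diencephalon-R_91	Diencephalon-R	right
92	ROI_Hippocampus-L_92	Hippocampus-L	left
93	ROI_Hippocampus-R_93	Hippocampus-R	right
94	ROI_Pallidum-L_94	Pallidum-L	left
95	ROI_Pallidum-R_95	Pallidum-R	right
96	ROI_Putamen-L_96	Putamen-L	left
97	ROI_Putamen-R_97	Putamen-R	right
98	ROI_Thalamus-L_98	Thalamus-L	left
99	ROI_Thalamus-R_99	Thalamus-R	right
100	ROI_Brainstem_100	Brainstem	none
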