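index	name	hemisphere	tissue_class
0	left_bankssts	left	cortical
1	left_caudal_anterior_cingulate	left	cortical
2	left_caudal_middle_frontal	left	cortical
3	left_cuneus	left	cortical
4	left_entorhinal	left	cortical
5	left_frontal_pole	left	cortical
6	left_fusiform	left	cortical
7	left_inferior_parietal	left	cortical
8	left_inferior_temporal	left	cortical
9	left_insula	left	cortical
10	left_isthmus_cingulate	left	cortical
11	left_lateral_occipital	left	cortical
12	left_lateral_orbitofrontal	left	cortical
13	left_lingual	left	cortical
14	left_medial_orbitofrontal	left	cortical
15	left_middle_temporal	left	cortical
16	left_paracentral	left	cortical
17	left_parahippocampal	left	cortical
18	left_pars_opercularis	left	cortical
19	left_pars_orbitalis	left	cortical
20	left_pars_triangularis	left	cortical
21	left_pericalcarine	left	cortical
22	left_postcentral	left	cortical
23	left_posterior_cingulate	left	cortical
24	left_precentral	left	cortical
25	left_precuneus	left	cortical
26	left_rostral_anterior_cingulate	left	cortical
27	left_rostral_middle_frontal	left	cortical
28	left_superior_frontal	left	cortical
29	left_superior_parietal	left	cortical
30	left_superior_temporal	left	cortical
31	left_supramarginal	left	cortical
32	left_temporal_pole	left	cortical
33	left_transverse_temporal	left	cortical
34	right_bankssts	right	cortical
35	right_caudal_anterior_cingulate	right	cortical
36	right_caudal_middle_frontal	right	cortical
37	right_cuneus	right	cortical
38	right_entorhinal	right	cortical
39	right_frontal_pole	right	cortical
40	right_fusiform	right	cortical
41	right_inferior_parietal	right	cortical
42	right_inferior_temporal	right	cortical
43	right_insula	right	cortical
44	right_isthmus_cingulate	right	cortical
45	right_lateral_occipital	right	cortical
46	right_lateral_orbitofrontal	right	cortical
47	right_lingual	right	cortical
48	right_medial_orbitofrontal	right	cortical
49	right_middle_temporal	right	cortical
50	right_paracentral	right	cortical
51	right_parahippocampal	right	cortical
52	right_pars_opercularis	right	cortical
53	right_pars_orbitalis	right	cortical
54	right_pars_triangularis	right	cortical
55	right_pericalcarine	right	cortical
56	right_postcentral	right	cortical
57	right_posterior_cingulate	right	cortical
58	right_precentral	right	cortical
59	right_precuneus	right	cortical
60	right_rostral_anterior_cingulate	right	cortical
61	right_rostral_middle_frontal	right	cortical
62	right_superior_frontal	right	cortical
63	right_superior_parietal	right	cortical
64	right_superior_temporal	right	cortical
65	right_supramarginal	right	cortical
66	right_temporal_pole	right	cortical
67	right_transverse_temporal	right	cortical
68	left_thalamus	left	subcortical
69	left_caudate	left	subcortical
70	left_putamen	left	subcortical
71	left_pallidum	left	subcortical
72	left_hippocampus	left	subcortical
73	left_amygdala	left	subcortical
74	left_accumbens	left	subcortical
75	left_cerebellum_cortex	left	subcortical
76	right_thalamus	right	subcortical
77	right_caudate	right	subcortical
78	right_putamen	right	subcortical
79	right_pallidum	right	subcortical
80	right_hippocampus	right	subcortical
81	right_amygdala	right	subcortical
82	right_accumbens	right	subcortical
83	right_cerebellum_cortex	right	subcortical
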