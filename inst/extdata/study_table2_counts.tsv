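tissue	singletons	duplicates	printed_ratio	printed_p
Total	305	114	2.68	NA
Anther	142	78	1.82	0.031
Ear_6week	72	64	1.12	1.64e-05
Ear_8week	74	68	1.09	5.39e-06
Ear_9week	72	74	0.97	2.17e-07
Ear_10week	55	54	1.02	8.21e-06
Early_prophase_meiocytes	131	85	1.54	3.91e-03
Embryo_1d	87	63	1.38	7.84e-04
Embryo_3week	57	46	1.24	5.78e-04
Embryo_9DAP	85	73	1.16	1.38e-05
Embryo_15DAP	89	66	1.35	4.24e-04
Embryo_20DAP	67	61	1.10	1.42e-05
Endosperm_9DAP	146	68	2.15	0.230
Endosperm_15DAP	155	70	2.21	0.296
Endosperm_20DAP	157	69	2.28	0.372
Leaf1_2week	126	74	1.70	1.32e-02
Leaf2_2week	102	83	1.23	1.98e-05
Leaf1_3week	122	71	1.72	1.65e-02
Leaf2_3week	101	74	1.36	3.16e-04
Leaf3_3week	92	76	1.21	2.44e-05
Leaf_4week	88	85	1.04	2.81e-07
Leaf_5week	77	82	0.94	3.29e-08
Leaf_6week	112	67	1.67	1.27e-02
Leaf_9week	116	85	1.36	1.67e-04
Leaf_expanded_4week	135	89	1.52	1.13e-03
Leaf_immature_5week	120	84	1.43	4.41e-04
Leaf_mature_5week	138	85	1.62	4.43e-03
Leaf_wrapped_4week	116	87	1.33	9.11e-05
Pollen_early	89	66	1.35	4.24e-04
Pollen_germination	54	45	1.20	4.00e-04
Pollen1_mature	70	49	1.43	3.43e-03
Pollen2_mature	84	46	1.83	4.31e-02
Root1_2week	96	79	1.22	2.09e-05
Root2_2week	112	66	1.70	1.62e-02
Seed	123	68	1.81	3.56e-02
Shoot_apical_meristem_4week	81	67	1.21	5.08e-05
Stalk_2week	103	81	1.27	4.81e-05
Silk_9week	64	78	0.82	1.77e-09
Silk_11week	115	84	1.37	1.88e-04
Silk_12week	101	89	1.13	1.92e-06
Tassel_4week	101	76	1.33	1.66e-04
Tassel_8week	65	58	1.12	2.93e-05
Tassel_9week	100	91	1.10	7.21e-07
Vegetative_apex_2week	72	64	1.12	1.64e-05
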