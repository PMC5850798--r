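term_id	term_name	n_expressed	n_observed	n_expected	fold	p	fdr
UBERON:2007001	Dorso-rostral cluster	18	9	1.88	4.79	2.91E-05	3.02E-03
UBERON:2007002	Ventro-rostral cluster	21	10	2.19	4.57	1.78E-05	2.00E-03
UBERON:2007003	Ventro-caudal cluster	19	9	1.99	4.52	5.01E-05	4.23E-03
UBERON:0000204	Ventral part of telencephalon	102	25	10.66	2.35	3.48E-05	3.36E-03
UBERON:0002946	Regional part of cerebellum	79	19	8.26	2.30	3.86E-04	2.74E-02
UBERON:0002757	Regional part of epithalamus	546	121	57.06	2.12	1.30E-16	8.78E-14
UBERON:0008904	Neuromast	169	37	17.66	2.10	8.91E-06	1.09E-03
UBERON:0000203	Pallium	105	23	10.97	2.10	4.27E-04	2.88E-02
UBERON:0003895	Hypaxial myotome region	101	22	10.55	2.09	6.13E-04	3.76E-02
UBERON:0010134	Secretory circumventricular organ	478	104	49.95	2.08	8.10E-14	3.64E-11
UBERON:0003902	Retinal neural layer	633	136	66.15	2.06	2.09E-17	2.82E-14
UBERON:0003296	Gland of diencephalon	559	115	58.42	1.97	1.70E-13	5.73E-11
UBERON:0002540	Lateral line system	519	101	54.24	1.86	6.78E-06	9.15E-04
UBERON:0001898	Hypothalamus	329	59	34.38	1.72	6.10E-04	3.76E-02
UBERON:0000045	Ganglion	596	105	62.28	1.69	2.26E-08	5.07E-06
UBERON:0002199	Integument	565	97	59.04	1.64	3.51E-07	5.92E-05
UBERON:0001894	Diencephalon	1459	239	152.47	1.57	1.82E-03	9.82E-02
UBERON:0005725	Olfactory system	760	124	79.42	1.56	6.94E-08	1.34E-05
UBERON:0002298	Brainstem	624	101	65.21	1.55	3.79E-05	3.41E-03
UBERON:0003051	Ear vesicle	843	133	88.09	1.51	9.98E-07	1.50E-04
UBERON:0000489	Cavitated compound organ	1701	255	177.76	1.43	1.34E-08	3.63E-06
UBERON:0002028	Hindbrain	1600	225	167.2	1.35	7.71E-05	6.11E-03
UBERON:0000479	Tissue	4751	645	496.49	1.30	1.29E-03	7.27E-02
UBERON:0000955	Brain	3255	435	340.15	1.28	1.29E-04	9.70E-03
UBERON:0000483	Epithelium	3734	489	390.21	1.25	8.56E-04	5.02E-02
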