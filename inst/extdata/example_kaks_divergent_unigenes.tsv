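gene	dbar	substitution_type	ratio_ab	ka_ab	ks_ab	ratio_b_out	ka_b_out	ks_b_out	ratio_a_out	ka_a_out	ks_a_out
Ribosomal protein L24-like	0.950	NC	50.0000	0.002	4.5e-05	0.0188	0.024	1.257	0.0168	0.021	1.272
Serine protease 6	0.950	S	1.2455	0.023	0.019	0.2743	0.601	2.189	0.2903	0.607	2.092
CG16817	0.949	N	0.7325	0.007	0.009	0.0830	0.152	1.835	0.0762	0.151	1.988
CG2219	0.950	N	0.7302	0.009	0.013	0.1050	0.235	2.239	0.1073	0.289	2.697
CG13367	0.949	N	0.7168	0.002	0.003	0.0826	0.168	2.034	0.0838	0.167	1.997
Microtubule-associated protein 205	0.949	S	0.6091	0.018	0.030	0.2762	0.321	1.162	0.2852	0.325	1.139
Odorant-binding protein 99c	0.950	N	0.6038	0.030	0.049	0.1401	0.124	0.887	0.1281	0.122	0.953
CG9500	0.950	N	0.6025	0.036	0.059	0.1160	0.353	3.042	0.0869	0.337	3.877
Ribonuclear protein at 97D	0.950	NC	0.5627	0.017	0.031	0.0243	0.044	1.822	0.0225	0.040	1.767
Transferrin 3	0.943	N	0.5614	0.007	0.012	0.0522	0.088	1.684	0.0528	0.088	1.674
Mitochondrial ribosomal protein S2	0.950	S	0.5462	0.010	0.017	0.0311	0.083	2.676	0.0344	0.083	2.425
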