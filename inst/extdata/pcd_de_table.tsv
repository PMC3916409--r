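gene	alias	probe_id	mean_log2_case	mean_log2_control	direction	log2_fc	fold_change	t_pvalue	best_probe
ARMC4	NA	4200274	8.327165	9.390315	down	1.06315	2.089488	0.130237	FALSE
C19ORF52	DNAAF3	6290253	7.118648	6.746589	up	-0.372059	0.77267895	0.132469	FALSE
C21ORF59	NA	7040162	10.05058	10.54353	down	0.492947	1.407317	0.212658	TRUE
C6ORF206	RSPH9	840433	8.570299	9.296023	down	0.72572	1.653725749	0.135019	FALSE
CCDC103	NA	6770463	7.065492	7.691135	down	0.62564	1.542895124	0.240855	FALSE
CCDC114	NA	7210482	6.548517	8.35885	down	1.81033	3.507225031	0.017073	FALSE
CCDC40	NA	4150072	2.886536	2.4908	up	-0.395737	0.76010098	0.150259	TRUE
CCDC65	NA	2370228	7.4877	8.417493	down	0.929793	1.905002	0.151083	FALSE
DNAH11	NA	7330360	3.002923	5.663427	down	2.6605	6.322521334	0.004405	TRUE
DNAH5	NA	2350554	2.840433	5.349519	down	2.50909	5.692608957	0.003368	FALSE
DNAI1	NA	2810300	8.674844	9.844953	down	1.17011	2.250288539	0.040018	FALSE
DNAI2	NA	5960685	7.177193	8.689865	down	1.51267	2.85337626	0.006119	FALSE
DNAL1	NA	6100682	3.770269	5.508203	down	1.73793	3.335562329	0.007245	TRUE
DYX1C1	NA	3140523	4.361447	5.485308	down	1.123861	2.179294	0.071072	TRUE
HEATR2	NA	5290037	8.210407	8.386503	down	0.1761	1.129825525	0.494105	TRUE
HYDIN	NA	7550360	6.950931	9.07216	down	2.12123	4.350647105	0.000905	TRUE
KTU	DNAAF2	2490408	6.58843	6.791816	down	0.20339	1.151400704	0.579292	FALSE
LRRC50	DNAAF1	5550035	8.577057	10.22783	down	1.65077	3.140011842	0.010513	FALSE
LRRC6	NA	2350477	6.796389	7.90332	down	1.10693	2.153868244	0.08437	FALSE
ODF1	NA	3120427	2.669272	3.925799	down	1.25653	2.38920393	0.046691	FALSE
RPGR	NA	2750386	2.726082	3.783812	down	1.05773	2.081653578	0.065558	TRUE
RSHL3	RSPH4A	2630519	9.918507	10.80253	down	0.88402	1.845510569	0.187161	TRUE
RSPH1	NA	6020451	10.40699	11.50298	down	1.095986	2.137591	0.105587	FALSE
ZMYND10	NA	4540066	8.938617	10.15335	down	1.214728	2.320971	0.012449	FALSE
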