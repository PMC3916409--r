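gene	alias	category	mean_log2_case	mean_log2_control	direction	log2_fc	fold_change	wilcoxon_p	multi_probe
DNAH1	NA	IDA	7.099971713	8.823093021	down	1.72312131	3.301499231	0.002397602	FALSE
DNAH10	NA	IDA	2.845467386	2.930532774	down	0.08506539	1.060735818	0.297612503	TRUE
DNAH12L	NA	IDA	2.984792693	4.691691968	down	1.70689927	3.264584241	0.005496876	FALSE
DNAH2	NA	IDA	8.605120088	10.73227718	down	2.12715709	4.368557834	0.001398601	FALSE
DNAH3	NA	IDA	5.76933297	8.094913833	down	2.32558086	5.012675559	0.005605302	FALSE
DNAH7	NA	IDA	6.514024915	8.269907386	down	1.75588247	3.377328402	0.003796204	FALSE
DNHD2	NA	IDA	8.860690672	10.45193877	down	1.59124809	3.01309903	0.017982018	FALSE
DNHL1	NA	IDA	2.704540406	3.102569317	down	0.39802891	1.317706357	0.069468652	TRUE
WDR63	NA	IDA	6.410269672	8.011632917	down	1.60136324	3.034298967	0.017982018	FALSE
WDR78	NA	IDA	4.278425094	5.226285631	down	0.94786054	1.92900989	0.024775225	TRUE
DNAH11	NA	ODA	3.002922837	5.663426945	down	2.66050411	6.322539346	0.002598476	FALSE
DNAH5	NA	ODA	2.840433314	5.349519237	down	2.50908592	5.692592858	0.010311612	FALSE
DNAH9	NA	ODA	4.195042679	4.979603695	down	0.78456102	1.722568101	0.008791209	TRUE
DNAI1	NA	ODA	8.674843985	9.844952993	down	1.17010901	2.250286995	0.033166833	FALSE
DNAI2	NA	ODA	7.177192762	8.6898654	down	1.51267264	2.853381481	0.002397602	FALSE
DNAL1	NA	ODA	5.239162724	5.900496355	down	0.66133363	1.58154393	0.163836164	TRUE
TCTE1	NA	ODA	3.213232157	4.82357751	down	1.61034535	3.053249212	0.007662144	FALSE
TCTE3	NA	ODA	2.361725905	2.586822518	down	0.22509661	1.168855518	0.617456403	FALSE
RSPH3	NA	radial_spoke	7.413315798	7.836831773	down	0.42351598	1.341192183	0.227972028	FALSE
RSHL3	RSPH4A	radial_spoke	9.513876417	10.3676621	down	0.85378569	1.807236971	0.136063936	TRUE
NME5	RSPH23	radial_spoke	9.938877607	10.88896095	down	0.95008335	1.931984273	0.264335664	FALSE
RSPH1	NA	radial_spoke	10.4069913	11.50297723	down	1.09598593	2.137591135	0.072327672	FALSE
C6ORF206	RSPH9	radial_spoke	8.57029857	9.296022759	down	0.72572419	1.653730552	0.163836164	FALSE
RSPH10B	NA	radial_spoke	4.839311246	5.755622796	down	0.91631155	1.887284017	0.005994006	TRUE
PPIL6	RSPH12	radial_spoke	6.766706564	8.011535825	down	1.24482926	2.369905052	0.111888112	FALSE
DNAJB13	NA	radial_spoke	4.103136217	5.749770835	down	1.64663462	3.131024115	0.033166833	FALSE
DYNC2H1	NA	IFT	6.048332879	8.057745569	down	2.00941269	4.026182839	0.002397602	FALSE
DYNC2LI1	NA	IFT	5.614105936	5.886374416	down	0.27226848	1.20770532	0.264335664	TRUE
IFT122	NA	IFT	4.919297327	5.396632088	down	0.47733476	1.39216939	0.008791209	TRUE
IFT140	NA	IFT	6.501863507	7.674088316	down	1.17222481	2.253589598	0.017982018	FALSE
IFT172	NA	IFT	8.232366019	9.177805846	down	0.94543983	1.925775902	0.017982018	FALSE
IFT52	NA	IFT	6.3875103	6.531748043	down	0.14423774	1.105146586	0.303496503	TRUE
IFT57	NA	IFT	8.12299147	9.303622084	down	1.18063061	2.266758367	0.033166833	FALSE
IFT74	NA	IFT	7.712753509	8.095831669	down	0.38307816	1.304121386	0.227972028	FALSE
IFT80	NA	IFT	2.430337143	2.764181897	down	0.33384475	1.260367755	0.100406593	TRUE
IFT81	NA	IFT	3.80548032	4.32006191	down	0.51458159	1.428579763	0.194205794	TRUE
IFT88	NA	IFT	4.97817553	5.909540297	down	0.93136477	1.907079214	0.033166833	TRUE
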