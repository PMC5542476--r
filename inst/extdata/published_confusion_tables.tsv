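table	dataset	comparison	model	gene	tp	fn	fp	tn	f1_published
1	GSE42026	viral_vs_bacterial	kmeans	NA	33	7	8	11	0.81
1	GSE60244	viral_vs_bacterial	kmeans	NA	55	1	16	21	0.87
1	GSE72809	viral_vs_bacterial	kmeans	NA	77	15	18	34	0.82
1	GSE72810	viral_vs_bacterial	kmeans	NA	27	1	5	18	0.90
2	GSE17755	sle_vs_jia	kmeans	NA	50	7	1	21	0.93
2	GSE29536	sle_vs_sjia	kmeans	NA	86	10	18	49	0.86
2	GSE22098	sle_vs_staphylococcus	kmeans	NA	78	4	7	45	0.93
3	GSE19743	burn_vs_healthy	logistic	HP	112	2	1	62	0.99
3	GSE80496	sepsis_vs_healthy	logistic	HP	24	0	0	21	1.00
3	GSE11375	injury_vs_healthy	logistic	HP	155	3	0	26	0.99
3	GSE68004	kawasaki_vs_healthy	logistic	ANXA3	75	1	4	33	0.97
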