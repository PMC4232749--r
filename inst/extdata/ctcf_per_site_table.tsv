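fra	ctcf_count	ctcf_pct_of_genome	ctcf_per_kb	h3k27ac_mean	cons_score
FRA1E	97	0.002	0.261	1.32	0.133
FRA1H	17338	0.372	1.631	3.07	
FRA2Ctel	700	0.015	0.938	2.53	0.071
FRA2Ccen	1108	0.024	1.486	1.56	0.111
FRA2G	1501	0.032	1.698	4.22	0.114
FRA2H	132	0.003	0.255	1.44	0.103
FRA3B	4156	0.089	0.982	1.57	0.105
FRA4F	4765	0.102	0.671	1.63	0.085
FRA6H	33735	0.724	3.607	8.14	0.12
FRA6F	2104	0.045	2.123	2.93	0.126
FRA6E	6274	0.135	1.081	2.47	0.062
FRA7B	23331	0.5	1.907	3.13	
FRA7E	4253	0.091	0.961	1.6	0.082
FRA7K	265	0.006	0.709	2.56	0.097
FRA7G	265	0.006	1.489	2.46	0.098
FRA7H	1458	0.031	3.283	4.38	0.089
FRA7I	435	0.009	0.3	1.98	0.065
FRA8C	8599	0.184	2.079	3.26	0.082
FRA9G	168	0.004	0.455	1.2	0.142
FRA10F	5878	0.126	2.051	2.57	0.071
FRA11E	4494	0.096	2.314	4.05	0.123
FRA11G	9545	0.205	2.136	2.57	0.126
FRA13A	193	0.004	0.302	1.23	0.108
FRA13E	2950	0.063	0.951	1.78	0.104
FRA16D	378	0.008	1.215	1.87	0.118
FRAXB	718	0.015	0.753	1.54	0.056
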