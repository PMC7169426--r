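dataset	samples	probes	classes	sdr_published	type
GSE3744	47	54675	2	0.00086	Breast cancer
GSE25099	79	17881	2	0.00441	Oral cancer
GSE26712	195	22283	2	0.00875	Ovarian cancer
GSE2280	27	22283	2	0.00121	Squamous cell carcinoma
GSE7670	66	22283	2	0.00296	Lung cancer
GSE4290	180	54613	2	0.00329	Brain cancer
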