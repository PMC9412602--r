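# GWAS summary statistics for instruments of a systemic iron-status biomarker (Iron Status Genetics Consortium meta-analysis, n = 48,972).
# The other_allele column (and outcome-side EAF) is SYNTHETIC fixture metadata chosen to be non-palindromic; it is not part of the published summary table.
snp_id	gene	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n
rs1800562	HFE	6	26093141	A	G	0.067	0.204	0.016	1.54e-38	48972
rs1799945	HFE	6	26091179	C	T	0.85	-0.065	0.01	1.71e-10	48972
rs855791	TMPRSS6	22	37462936	A	G	0.446	-0.055	0.007	1.38e-14	48972
rs744653	WDR75-SLC40A1	2	190000000	T	C	0.854	-0.089	0.01	8.37e-19	48972
rs651007	ABO	9	136000000	T	C	0.202	-0.05	0.009	1.31e-08	48972
rs411988	TEX14	17	56709034	A	G	0.564	-0.044	0.007	1.59e-10	48972
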