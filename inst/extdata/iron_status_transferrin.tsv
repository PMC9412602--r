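# GWAS summary statistics for instruments of a systemic iron-status biomarker (Iron Status Genetics Consortium meta-analysis, n = 48,972).
# The other_allele column (and outcome-side EAF) is SYNTHETIC fixture metadata chosen to be non-palindromic; it is not part of the published summary table.
snp_id	gene	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n
rs1800562	HFE	6	26093141	A	G	0.067	-0.479	0.016	8.90e-196	48972
rs1799945	HFE	6	26091179	C	T	0.85	0.114	0.01	9.36e-30	48972
rs855791	TMPRSS6	22	37462936	A	G	0.446	0.044	0.007	1.98e-09	48972
rs744653	WDR75-SLC40A1	2	190000000	T	C	0.854	0.068	0.01	1.35e-11	48972
rs8177240	TF	3	133000000	T	C	0.669	-0.38	0.007	8.43e-610	48972
rs9990333	TFRC	3	196000000	T	C	0.46	-0.051	0.007	1.95e-13	48972
rs4921915	NAT2	8	18272466	A	G	0.782	0.079	0.009	7.05e-19	48972
rs6486121	ARNTL	11	13355770	T	C	0.631	-0.046	0.007	3.89e-10	48972
rs174577	FADS2	11	61604814	A	C	0.33	0.062	0.007	2.28e-17	48972
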