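# GWAS summary statistics for instruments of a systemic iron-status biomarker (Iron Status Genetics Consortium meta-analysis, n = 48,972).
# The other_allele column (and outcome-side EAF) is SYNTHETIC fixture metadata chosen to be non-palindromic; it is not part of the published summary table.
snp_id	gene	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n
rs1800562	HFE	6	26093141	A	G	0.067	0.577	0.016	2.19e-270	48972
rs1799945	HFE	6	26091179	C	T	0.85	-0.231	0.01	5.13e-109	48972
rs855791	TMPRSS6	22	37462936	A	G	0.446	-0.19	0.008	6.41e-137	48972
rs8177240	TF	3	133000000	T	C	0.669	0.1	0.008	7.24e-38	48972
rs7385804	TFR2	7	100000000	A	G	0.621	0.054	0.008	6.07e-12	48972
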