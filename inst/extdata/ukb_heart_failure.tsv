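# SNP-heart-failure associations (Neale-lab UK Biobank analysis; the source reports both 1088/360,106 and 1405/359,789 cases/controls; total n = 361,194).
# The other_allele column (and outcome-side EAF) is SYNTHETIC fixture metadata chosen to be non-palindromic; it is not part of the published summary table.
snp_id	gene	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n
rs1800562	HFE	6	26093141	A	G	0.067	-1.74e-04	0.00027	0.515	361194
rs1799945	HFE	6	26091179	C	T	0.85	1.32e-04	0.0002	0.511	361194
rs855791	TMPRSS6	22	37462936	A	G	0.446	-1.02e-04	0.00015	0.486	361194
rs744653	WDR75-SLC40A1	2	190000000	T	C	0.854	1.35e-04	0.00021	0.516	361194
rs651007	ABO	9	136000000	T	C	0.202	5.88e-04	0.00018	0.001	361194
rs411988	TEX14	17	56709034	A	G	0.564	1.95e-04	0.00015	0.178	361194
rs8177240	TF	3	133000000	T	C	0.669	-9.63e-05	0.00015	0.526	361194
rs7385804	TFR2	7	100000000	A	G	0.621	-9.27e-05	0.00015	0.533	361194
rs9990333	TFRC	3	196000000	T	C	0.46	-6.56e-05	0.00014	0.651	361194
rs4921915	NAT2	8	18272466	A	G	0.782	-8.05e-05	0.00017	0.643	361194
rs6486121	ARNTL	11	13355770	T	C	0.631	-2.03e-04	0.00015	0.176	361194
rs174577	FADS2	11	61604814	A	C	0.33	1.45e-04	0.00015	0.338	361194
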