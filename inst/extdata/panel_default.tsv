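# Default 9-SNP type-2-diabetes risk panel.
# or_literature and risk_allele_freq are editable defaults: plausible
# European-ancestry per-allele odds ratios and frequencies from the GWAS
# literature, NOT cohort-specific estimates. Re-orient rows so that
# or_literature >= 1 for the listed risk allele before loading.
# other_allele and risk_allele_freq are optional columns used when writing
# VCF fixtures and when simulating cohorts.
rsid	gene	risk_allele	other_allele	or_literature	secretion_related	risk_allele_freq
rs7903146	TCF7L2	T	C	1.37	TRUE	0.30
rs7923837	HHEX	G	A	1.13	TRUE	0.60
rs13266634	SLC30A8	C	T	1.12	TRUE	0.70
rs1001013	WFS1	G	A	1.11	TRUE	0.60
rs5219	KCNJ11	T	C	1.14	TRUE	0.40
rs151290	KCNQ1	C	A	1.20	TRUE	0.15
rs10830963	MTNR1B	G	C	1.09	TRUE	0.30
rs8050136	FTO	A	C	1.17	FALSE	0.40
rs1808282	PPARG	C	G	1.14	FALSE	0.85
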