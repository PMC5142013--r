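# 26 pan-cancer TF-miRNA feed-forward loops (dysregulated in >= 5 tumor types)
# columns: tf, mirna, gene, ffl_type, n_tumor_types
tf	mirna	gene	ffl_type	n_tumor_types
E2F1	hsa-miR-195-5p	CCNE1	TF-FFL	9
E2F1	hsa-miR-195-5p	BCL2	TF-FFL	7
E2F1	hsa-miR-15a-5p	CCNE1	TF-FFL	6
E2F1	hsa-miR-195-5p	CCND1	TF-FFL	6
ETS1	hsa-miR-21-5p	MMP9	TF-FFL	6
ETS1	hsa-miR-21-5p	DAXX	TF-FFL	6
TP53	hsa-miR-145-5p	NDRG2	TF-FFL	6
E2F1	hsa-miR-34a-5p	CCND1	miRNA-FFL	6
E2F1	hsa-miR-34a-5p	BCL2	miRNA-FFL	6
E2F1	hsa-miR-17-5p	BCL2	FB-FFL	6
E2F1	hsa-miR-15b-5p	CCNE1	TF-FFL	5
E2F1	hsa-miR-16-5p	CCNE1	TF-FFL	5
EGR1	hsa-miR-130b-3p	LDLR	TF-FFL	5
JUN	hsa-miR-21-5p	MSH2	TF-FFL	5
JUNB	hsa-miR-21-5p	HPGD	TF-FFL	5
JUND	hsa-miR-21-5p	MMP9	TF-FFL	5
SNAI2	hsa-miR-200b-3p	ZEB1	TF-FFL	5
SNAI2	hsa-miR-200c-3p	ZEB1	TF-FFL	5
TP53	hsa-miR-145-5p	ZFP36	TF-FFL	5
TWIST1	hsa-miR-200b-3p	ZEB1	TF-FFL	5
E2F1	hsa-miR-34a-5p	CCND3	miRNA-FFL	5
E2F1	hsa-miR-181b-5p	BCL2	miRNA-FFL	5
CREB1	hsa-miR-182-5p	CCND2	miRNA-FFL	5
MITF	hsa-miR-182-5p	BCL2	miRNA-FFL	5
ETS1	hsa-miR-125b-5p	ERBB2	miRNA-FFL	5
E2F1	hsa-miR-20b-5p	BRCA1	FB-FFL	5
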