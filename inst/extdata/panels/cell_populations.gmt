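T_cells	illustrative default markers (8 immune + 2 stromal population panels); replace with curated lists	CD3D	CD3E	CD3G	CD28	CD6	TRAT1
CD8_T_cells	illustrative default markers; replace with curated lists	CD8A	CD8B
Cytotoxic_lymphocytes	illustrative default markers; replace with curated lists	GZMA	GZMB	PRF1	KLRD1	NKG7
B_lineage	illustrative default markers; replace with curated lists	CD19	MS4A1	CD79A	CD79B	PAX5	IGKC
NK_cells	illustrative default markers; replace with curated lists	NCR1	KIR2DL1	KIR3DL1	NCAM1	KLRF1
Monocytic_lineage	illustrative default markers; replace with curated lists	CD14	CD68	CSF1R	ITGAM	FCGR1A
Myeloid_dendritic_cells	illustrative default markers; replace with curated lists	CD1A	CD1B	CD1E	CLEC10A	FLT3
Neutrophils	illustrative default markers; replace with curated lists	FCGR3B	CEACAM8	CSF3R	S100A12	FPR1
Endothelial_cells	illustrative default markers; replace with curated lists	PECAM1	VWF	CDH5	KDR	CLDN5
Fibroblasts	illustrative default markers; replace with curated lists	PDGFRA	COL5A1	COL6A1	TAGLN	MMP2
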