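TIL_lymphoid	illustrative default lymphoid markers; replace with a curated 10-gene panel	CD3D	CD3E	CD3G	CD2	CD7	IL7R	LTB	TRBC1	TRAC	SKAP1
TIL_myeloid	illustrative default myeloid markers; replace with a curated 10-gene panel	CD14	CD68	CD163	FCGR3A	ITGAM	CSF1R	LYZ	AIF1	MS4A7	FCER1G
TIL_stromal	illustrative default stromal markers; replace with a curated 10-gene panel	COL1A1	COL1A2	COL3A1	FAP	PDGFRB	THY1	DCN	LUM	FN1	ACTA2
TIL_cancer	illustrative default epithelial/cancer markers; replace with a curated 10-gene panel	EPCAM	KRT8	KRT18	KRT19	CDH1	ESR1	KRT7	MUC1	GATA3	FOXA1
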