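IFN_gamma	illustrative interferon-gamma response metagene; replace with the curated component list	IFNG	STAT1	IDO1	CXCL9	CXCL10	CXCL11
ICK	illustrative immune-checkpoint metagene; replace with the curated component list	PDCD1	CTLA4	LAG3	HAVCR2	TIGIT	CD274	ICOS	BTLA
CYTOX	illustrative cytotoxicity metagene; replace with the curated component list	GZMH	GZMK	GNLY	NKG7	KLRB1	KLRK1	FGFBP2
Th1	illustrative Th1-orientation metagene; replace with the curated component list	TBX21	STAT4	IL12RB2	CXCR3	CCR5	IL2
CTL	illustrative cytotoxic-lymphocyte metagene; replace with the curated component list	CD8A	CD8B	GZMA	GZMB	PRF1	EOMES
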