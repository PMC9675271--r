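Proliferation	illustrative proliferation signature; replace with the curated component list	MKI67	CCNB1	CDC20	BUB1	PLK1	AURKA	TOP2A	RRM2	TYMS	BIRC5
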