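G1S_example	abridged example G1/S phase gene set; supply the full literature set for real analyses	MCM2	MCM4	MCM6	PCNA	CDC6	CDC45	CCNE2	UNG	RRM1	RRM2	GINS2	E2F8
G2M_example	abridged example G2/M phase gene set; supply the full literature set for real analyses	CCNB1	CCNB2	CDK1	TOP2A	BUB1	AURKA	AURKB	PLK1	MKI67	CENPA	UBE2C	BIRC5
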