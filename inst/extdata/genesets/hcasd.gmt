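hcASD	high-confidence autism spectrum disorder genes (9 genes)	ANK2	CHD8	CUL3	DYRK1A	GRIN2B	KATNAL2	POGZ	SCN2A	TBR1
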