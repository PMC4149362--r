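network	role	gene
ttest	hub	YWHAZ
ttest	hub	YWHAB
ttest	hub	YWHAE
ttest	hub	MAPK1
ttest	hub	DISC1
ttest	hub	APP
ttest	hub	VCL
ttest	hub	VIM
ttest	hub	HSPA1A
ttest	hub	IKBKB
ttest	hub	YWHAQ
ttest	hub	SNCA
ttest	hub	SQSTM1
ttest	bottleneck	HDAC4
ttest	bottleneck	TGFB1
ttest	bottleneck	SET
ttest	bottleneck	SPTBN1
ttest	bottleneck	RAD23A
ttest	bottleneck	RPS3
ttest	bottleneck	CHUK
ttest	bottleneck	DAPK1
ttest	bottleneck	IGF1R
ttest	bottleneck	IRAK1
ttest	bottleneck	CYCS
ttest	bottleneck	MAP2K4
ttest	bottleneck	SRRM2
ttest	bottleneck	PHB
ttest	bottleneck	YWHAH
sam	hub	YWHAZ
sam	hub	YWHAB
sam	hub	CDC42
sam	bottleneck	PRKCZ
sam	bottleneck	APC
sam	bottleneck	SNCA
sam	bottleneck	NFKBIA
sam	bottleneck	TSC2
sam	bottleneck	IGF1R
sam	bottleneck	HSPA1A
sam	bottleneck	TH
sam	bottleneck	ATP5A1
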