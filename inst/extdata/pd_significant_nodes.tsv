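network	role	gene
ttest	hub	YWHAZ
ttest	hub	ACTB
ttest	hub	ACTG1
ttest	hub	YWHAB
ttest	hub	YWHAE
ttest	hub	MAPK1
ttest	hub	MAP3K14
ttest	hub	DISC1
ttest	hub	APP
ttest	hub	VCL
ttest	hub	VIM
ttest	hub	FTSJ1
ttest	hub	HSPA1A
ttest	hub	IKBKB
ttest	hub	YWHAQ
ttest	hub	ARRB2
ttest	hub	EEF1A1
ttest	hub	SNCA
ttest	hub	SQSTM1
ttest	bottleneck	HDAC4
ttest	bottleneck	TGFB1
ttest	bottleneck	STUB1
ttest	bottleneck	ANXA2
ttest	bottleneck	KPNB1
ttest	bottleneck	SET
ttest	bottleneck	STX1A
ttest	bottleneck	SPTBN1
ttest	bottleneck	AXIN1
ttest	bottleneck	IQGAP1
ttest	bottleneck	RAD23A
ttest	bottleneck	RPS3
ttest	bottleneck	CHUK
ttest	bottleneck	MCL1
ttest	bottleneck	DAPK1
ttest	bottleneck	PARD3
ttest	bottleneck	TJP2
ttest	bottleneck	ACTN2
ttest	bottleneck	TAF9
ttest	bottleneck	IGF1R
ttest	bottleneck	CDC25B
ttest	bottleneck	IARS
ttest	bottleneck	CTNNA1
ttest	bottleneck	PTPN3
ttest	bottleneck	IRAK1
ttest	bottleneck	TFRC
ttest	bottleneck	VASP
ttest	bottleneck	MAP3K7IP2
ttest	bottleneck	ADAM17
ttest	bottleneck	CYCS
ttest	bottleneck	MAP2K4
ttest	bottleneck	WEE1
ttest	bottleneck	SF3B1
ttest	bottleneck	DSTN
ttest	bottleneck	SRRM2
ttest	bottleneck	BAG2
ttest	bottleneck	C1QBP
ttest	bottleneck	PHB
ttest	bottleneck	YWHAH
ttest	bottleneck	GSN
ttest	bottleneck	MARCKS
sam	hub	YWHAZ
sam	hub	YWHAB
sam	hub	CSNK2A1
sam	hub	CLTC
sam	hub	CDC42
sam	bottleneck	PRKCZ
sam	bottleneck	APC
sam	bottleneck	SNCA
sam	bottleneck	NFKBIA
sam	bottleneck	IQGAP1
sam	bottleneck	TSC2
sam	bottleneck	IGF1R
sam	bottleneck	HSPA1A
sam	bottleneck	OCRL
sam	bottleneck	PARD3
sam	bottleneck	CLTB
sam	bottleneck	TH
sam	bottleneck	ATP5A1
sam	bottleneck	TUBB
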