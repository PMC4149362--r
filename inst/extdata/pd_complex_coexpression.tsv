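network	node1	node2	r_control	r_disease	complex
ttest	CD2BP2	PRPF8	0.182452	0.377959	Spliceosome (ID: 351)
ttest	CD2BP2	SF3A2	-0.49456	0.300699	Spliceosome (ID: 351)
ttest	CD2BP2	WBP11	0.064197	-0.18898	Spliceosome (ID: 351)
ttest	PRPF8	SF3A2	-0.09299	-0.01542	Spliceosome (ID: 351)
ttest	SF3A2	SF3B1	0.236131	-0.15777	Spliceosome (ID: 351)
ttest	SF3A2	SRRM2	0.210102	0.531593	Spliceosome (ID: 351)
ttest	SF3A2	WBP11	-0.10021	-0.16228	Spliceosome (ID: 351)
ttest	ACTB	ACTG1	0.344993	0.571264	Polybromo and BAF containing complex (ID: 149, 189)
ttest	ACTB	SMARCA4	0.272319	0.085326	Polybromo and BAF containing complex (ID: 149, 189)
ttest	ACTG1	NF2	-0.2271	0.0839	Polybromo and BAF containing complex (ID: 149, 189)
ttest	SMARCA4	SMARCC1	-0.32228	-0.2122	Polybromo and BAF containing complex (ID: 149, 189)
ttest	SMARCC1	SMARCC2	0.197918	0.250794	Polybromo and BAF containing complex (ID: 149, 189)
ttest	MAP2K1	MAPK1	0.705468	0.59637	Ksr1 complex (ID: 5909, 5937)
ttest	YWHAE	YWHAH	-0.30185	-0.16978	Ksr1 complex (ID: 5909, 5937)
ttest	YWHAE	YWHAZ	-0.24657	-0.06473	Ksr1 complex (ID: 5909, 5937)
ttest	PSMC4	PSMD1	0.305936	0.155939	Proteasome (ID: 181, 193)
ttest	PSMC4	PSMD4	0.030223	0.49093	Proteasome (ID: 181, 193)
ttest	PSMD1	PSMD4	0.129277	0.429546	Proteasome (ID: 181, 193)
ttest	EEF1A1	RPLP1	-0.62308	-0.37849	Nop56p-associated pre-rRNA complex (ID: 3055)
ttest	PRPF8	SF3A2	-0.09299	-0.01542	C complex spliceosome (ID: 1181)
ttest	SF3A2	SF3B1	0.236131	-0.15777	C complex spliceosome (ID: 1181)
ttest	SF3A2	SRRM2	0.210102	0.531593	C complex spliceosome (ID: 1181)
sam	AMPH	AP2A2	0.895323	0.711618	Epsin-clathrin complex (ID: 1228)
sam	AP2A2	AP2M1	0.896811	0.71299	Epsin-clathrin complex (ID: 1228)
sam	AP2A2	EPS15	0.680562	0.130673	Epsin-clathrin complex (ID: 1228)
sam	AMPH	CLTC	0.835258	0.766836	Endocytic coat complex (ID: 5344)
sam	AMPH	DNM1	0.859907	0.771107	Endocytic coat complex (ID: 5344)
sam	CLTC	EPS15	0.594193	0.346006	Endocytic coat complex (ID: 5344)
sam	CLTC	SYNJ1	0.645271	0.769517	Endocytic coat complex (ID: 5344)
sam	DNM1	EPS15	0.752444	0.283483	Endocytic coat complex (ID: 5344)
sam	EPS15	SYNJ1	0.694805	0.449957	Endocytic coat complex (ID: 5344)
sam	PSMA1	PSMB2	0.389236	0.512285	Proteasome complex (ID: 181, 191, 192, 193, 194)
sam	PSMA1	PSMB7	0.515788	0.620496	Proteasome complex (ID: 181, 191, 192, 193, 194)
sam	PSMB2	PSMB7	0.102045	0.310781	Proteasome complex (ID: 181, 191, 192, 193, 194)
sam	APC	IQGAP1	-0.61332	-0.33299	APC-IQGAP1-Rac1 complex (ID: 3011), APC-IQGAP1-Cdc42 complex (ID: 3012)
sam	CDC42	IQGAP1	-0.18484	-0.2834	APC-IQGAP1-Rac1 complex (ID: 3011), APC-IQGAP1-Cdc42 complex (ID: 3012)
sam	CDC42	PARD3	-0.13129	-0.35908	CDC42-Par6c-Par3-Prkcz complex (ID: 804), Tiam1-Par-3-aPKC-zeta complex (ID: 1023)
sam	CDC42	PRKCZ	0.762057	0.706097	CDC42-Par6c-Par3-Prkcz complex (ID: 804), Tiam1-Par-3-aPKC-zeta complex (ID: 1023)
sam	PARD3	PRKCZ	-0.13645	-0.44763	CDC42-Par6c-Par3-Prkcz complex (ID: 804), Tiam1-Par-3-aPKC-zeta complex (ID: 1023)
sam	CSNK2A1	YWHAB	0.253246	0.672328	Ksr1-CK2-MEK-14-3-3 complex, PDGF treated (ID: 5936)
sam	TH	YWHAB	-0.47327	0.157579	Ksr1-CK2-MEK-14-3-3 complex, PDGF treated (ID: 5936)
sam	TH	YWHAZ	-0.36101	-0.1174	Ksr1-CK2-MEK-14-3-3 complex, PDGF treated (ID: 5936)
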