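gene	dopaminergic	cholinergic	serotonergic	adrenergic	glutamatergic	GABAergic
ARRB2	+	-	-	+	-	-
STX1A	+	-	+	-	+	+
TFRC	+	-	-	-	-	-
MARCKS	+	-	+	+	-	-
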