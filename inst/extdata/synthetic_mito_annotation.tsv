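gene	start	end	strand	frame	type
rrnS_synthetic	70	1020	+	0	rRNA
rrnL_synthetic	1090	2650	+	0	rRNA
nd1_synthetic	2750	3698	+	0	coding
nd2_synthetic	3910	4948	+	0	coding
cox1_synthetic	5300	6839	+	0	coding
cox2_synthetic	7000	7690	+	0	coding
atp6_synthetic	7900	8578	+	0	coding
cox3_synthetic	8580	9360	+	0	coding
nd3_synthetic	9420	9765	+	0	coding
nd4_synthetic	10050	11430	+	0	coding
nd5_synthetic	11600	13400	+	0	coding
nd6_synthetic	13400	13919	-	0	coding
cytb_synthetic	13990	14920	+	0	coding
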