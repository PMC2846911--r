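est_id	exon5	five_frag	three_frag	exon3	length	burge	rule	fate	ortholog
EX501652.1	AGA	ATATCCTTTC	TTGGGCATTGTTATATTTCCTTAACGGGTATGGTTTAC	GTT	2095	+	+	U12->U2	EEED8.7
EX500683.1	ATT	ATATCCTTTC	AATTTCATTTCCTTAACGTTAGATTTTTGTTGTTTTAC	TGA	94	+	+	U12 lost	E04D5.1a
ES570647.1	ATC	ATATCCTTTC	GTATTGTTTGTATTTTCCTTAACTTCATATGTTTTTAC	GTA	182	+	+	U12 lost	Y37D8A.10
EX499999.1	GAG	GTATCCTTTG	TTTTGTTTTTCTCTCTTTTTACAATTATTATACAG	GCC	90	-	+	U12->U2	F10F2.1
ES570692.1	TAG	GTATTGTTTT	TGCTACAAGGAATTTTTTTATTGCTTTGATTTTAG	AGT	617	-	-	U12->U2	F40F8.10
ES561213.1	TCG	GTATTATTTT	CATATTAATCGTTTCATTTCTTAATGTATTTTTAG	TGG	54	-	-	U12->U2	ZC395.10
EX500486.1	TCG	GTATTCTTTC	TAATATGTTTTTCTTTTTTTTCAACTTATTTTAAG	ATT	87	-	+	U12->U2	ZC328.3a
ES569928.1	ATG	GTATTCTTTT	ATTTCCATTACAAAATTACAACCGCGTTGTTCTTTCAG	TGC	107	+	+	Not known	Y82E9BR.15
ES565768.1	CAG	GTATTCTTTT	CAAATTTTGGAAAAATTCTTTTTTTTTAATCCGAACAG	GTA	94	-	+	Not known	C34D4.4a
ES562099.1	AAT	GTATCCTTAA	TGTATGAGGTTTGGTATTTCTGATTTTAATCATTTTAG	TGT	50	-	+	Not known	R07E5.14
ES563059.1	GCG	GTATCTTTTC	TATTTATAACTGAATCGTTTTTATTAATAATTTTTTAG	AGT	54	-	+	Not known	M04F3.4
BQ738460.1	ACG	GTATCGTTCA	TCAATTTTTTTAAAAGTAATTTTCTTCATATATTTTAG	AAC	72	-	-	U12 lost/Not known	Y56A3A.36
ES566079.1	TGG	GTATCGTTCG	ATTAACTAACACTTTGAAGTTGACAAGTGAATGTTTAG	GAT	140	-	-	Not known	M02B7.4
EX500543.1	TCG	GTATTCTTTG	TTATTATTAATTTCTGTTTTTTTTGGTTTTCTAAACAG	AGA	86	-	+		None
ES561535.1	GGG	GTATTATTTT	TTTTCTGTGATTTAATTGCATTTTAATGTTCTATCTAG	TGA	71	-	-		None
BQ738918.1	GAA	GTATCTTTTA	TGAATTTTGCTAAATTGTACTTAACAGGTTGTTTTTAG	AAA	153	-	+		None
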