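pair_id	a_species	a_protein	a_introns	b_species	b_protein	b_introns	expected_fate
EX501652.1	T_spiralis	MSDLKAVETRFGNPQWHYICMSDLKAVETR	12:0:AT_AC:1	C_elegans	MSDLKAVETRFGNPQWHYICMSDLKAVETR	15:0:GT_AG:0	U12_TO_U2_SHIFTED
EX500683.1	T_spiralis	MSDLKAVETRFGNPQWHYICMSDLKAVETR	10:1:AT_AC:1	C_elegans	MSDLKAVETRFGNPQWHYICMSDLKAVETR		U12_LOST
ES570647.1	T_spiralis	MSDLKAVETRFGNPQWHYICMSDLKAVETR	8:2:AT_AC:1	C_elegans	MSDLKAVETRFGNPQWHYICMSDLKAVETR		U12_LOST
EX499999.1	T_spiralis	MSDLKAVETRFGNPQWHYICMSDLKAVETR	14:0:GT_AG:1	C_elegans	MSDLKAVETRFGNPQWHYICMSDLKAVETR	14:0:GT_AG:0	U12_TO_U2_SAME_SITE
ES570692.1	T_spiralis	MSDLKAVETRFGNPQWHYICMSDLKAVETR	9:1:GT_AG:1	C_elegans	MSDLKAVETRFGNPQWHYICMSDLKAVETR	9:1:GT_AG:0	U12_TO_U2_SAME_SITE
ES561213.1	T_spiralis	MSDLKAVETRFGNPQWHYICMSDLKAVETR	20:2:GT_AG:1	C_elegans	MSDLKAVETRFGNPQWHYICMSDLKAVETR	20:2:GT_AG:0	U12_TO_U2_SAME_SITE
EX500486.1	T_spiralis	MSDLKAVETRFGNPQWHYICMSDLKAVETR	11:0:GT_AG:1	C_elegans	MSDLKAVETRFGNPQWHYICMSDLKAVETR	11:0:GT_AG:0	U12_TO_U2_SAME_SITE
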