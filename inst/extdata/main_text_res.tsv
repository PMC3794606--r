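name	sequence	spacer	provenance
GGGCA-full	GGGCATGCCCGGGCATGCCC	0	synthetic
GAACA-full	GAACATGTTCGAACATGTTC	0	synthetic
ConE	GAGCATGTCCGAGCATGTCC	0	synthetic
ConP	GGGCATGTCCGAGCATGTCC	0	synthetic
ConA-reconstructed	GGGCATGTCCGGGCATGTCC	0	synthetic
ConD-reconstructed	GGGCATGCCCGGGCATGCCC	0	synthetic
ConH-reconstructed	GGGCTTGCCCGGGCTTGCCC	0	synthetic
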