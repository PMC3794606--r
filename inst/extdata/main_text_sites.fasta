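>GGGCA_halfsite_probe 12-bp fluorescence-polarization probe
TGGGCATGCCCA
>GAACA_halfsite_probe 12-bp fluorescence-polarization probe
CGAACATGTTCG
>GGGCA_fullsite 20-bp full-site RE, 4/4 RY signature
GGGCATGCCCGGGCATGCCC
>GAACA_fullsite 20-bp full-site RE, 0/4 RY signature
GAACATGTTCGAACATGTTC
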