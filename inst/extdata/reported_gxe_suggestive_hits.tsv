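chrom	pos	rsid	gene	exposure	rr	ci_lower	ci_upper	p_reported
3	191830067	NA	FGF12	smoking	0.379	0.264	0.544	1.37e-7
9	113523091	rs2186801	MUSK	smoking	0.494	0.379	0.643	1.68e-7
15	92737555	rs8031462	SLCO3A1	alcohol	1.804	1.436	2.267	3.99e-7
1	15839112	rs4646022	CASP9	vitamin	1.807	1.427	2.288	9.06e-7
5	16509183	rs41117	RETREG1	vitamin	1.585	1.327	1.894	3.87e-7
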