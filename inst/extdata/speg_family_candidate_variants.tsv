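chrom	pos	ref	alt	gene	pop_af	n_healthy_hom	III3	III5	III6	II4	II5
2	220037393	a	g	C2orf24	0.99	NA	1/1	1/1	1/1	0/1	0/1
2	220250147	a	g	DNPEP	1	NA	1/1	1/1	1/1	0/1	0/1
2	220343876	g	a	SPEG	NA	NA	1/1	1/1	1/1	0/1	0/1
2	225721677	c	t	DOCK10	0.0072	9	1/1	1/1	1/1	0/1	0/1
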