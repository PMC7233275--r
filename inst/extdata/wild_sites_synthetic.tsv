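locus	locus_position	concat_position	type	snp_class	length	ref	A	B	C	D	E
atpI-atpH	54	54	substitution	2	1	T	T	G	T	T	T
atpI-atpH	120	120	substitution	2	1	G	G	G	T	G	G
atpI-atpH	150	150	indel	NA	7	ATTACTA	ATTACTA	ATTACTA	ATTACTA	-------	ATTACTA
ndhA	83	300	substitution	1	1	C	C	C	C	T	C
ndhA	173	390	substitution	2	1	A	A	A	C	A	A
ndhA	283	500	substitution	2	1	G	G	G	G	G	T
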