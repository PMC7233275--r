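primer_pair	pair	difference	specificity
MLT C1-MLT C4	C-D	T<->G & C<->A	18
MLT C1-MLT C4	B-C	A<->C	20
MLT C1-MLT C4	B-D	T<->G	29
MLT C1-MLT C4	A-C	GT<->TA, G<->T & T<->A	88
MLT C1-MLT C4	A-D	G<->T & T<->A	88
MLT C1-MLT C4	A-B	GT<->TA & G<->T	93
MLT C3-MLT C4	A-D	T<->A	11
MLT C3-MLT C4	A-B	8 bp indel & T<->A	22
MLT C3-MLT C4	B-D	8 bp indel	33
MLT C3-MLT C4	B-C	T<->G & 8 bp indel	65
MLT C3-MLT C4	C-D	G<->T	73
MLT C3-MLT C4	A-C	T<->G & T<->A	83
MLT M1-MLT M2	A-C	G<->T & A<->G	6
MLT M1-MLT M2	B-D	A<->G & G<->T	93
MLT S1-MLT S4	A-C	5 bp indel	0
MLT V1-MLT V2	A-C	6 bp indel, T<->A & T<->A	11
MLT V1-MLT V2	A-D	6 bp indel & T<->A	93
MLT V1-MLT V2	C-D	A<->T	96
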