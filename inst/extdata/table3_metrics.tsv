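primer_pair	haplotype	n	sensitivity	specificity	accuracy	flagged	note
MLT C1-MLT C4	A	14	71	94	88		
MLT C1-MLT C4	B	16	69	44	52		
MLT C1-MLT C4	C	11	91	49	58		
MLT C1-MLT C4	D	11	73	44	50		printed N (11) disagrees with cluster counts (8+1+3); N authoritative
MLT C3-MLT C4	A	14	100	43	57		
MLT C3-MLT C4	B	16	56	27	36		
MLT C3-MLT C4	C	12	58	79	75		
MLT C3-MLT C4	D	14	79	36	46		
MLT M1-MLT M2	A	15	93	98	97		
MLT M1-MLT M2	B	16	94	67	74		
MLT M1-MLT M2	C	14	93	98	97		
MLT M1-MLT M2	D	16	94	67	74		
MLT S1-MLT S2	A	12	100	100	100		
MLT S1-MLT S2	B	15	100	100	100		
MLT S1-MLT S2	C	11	100	100	100		
MLT S1-MLT S2	D	14	100	100	100		
MLT S1-MLT S4	A	14	100	79	83		
MLT S1-MLT S4	B	10	80	100	98		
MLT S1-MLT S4	C	14	100	79	83		
MLT S1-MLT S4	D	14	86	100	98		
MLT S1-MLT S4	E	16	100	100	100		
MLT S1-MLT S4	F	14	71	100	95		
MLT S3-MLT S4	A	15	100	100	100		
MLT S3-MLT S4	B	12	92	100	95	accuracy	printed accuracy incompatible with printed Sen/Spe (implies 99)
MLT S3-MLT S4	C	11	91	100	95	accuracy	printed accuracy incompatible with printed Sen/Spe (implies 99)
MLT S3-MLT S4	D	16	100	100	100		
MLT S3-MLT S4	E	14	93	100	95	accuracy	printed accuracy incompatible with printed Sen/Spe (implies 99)
MLT U1-MLT U2	A	16	100	100	100		
MLT U1-MLT U2	B	11	73	100	96		
MLT U1-MLT U2	C	15	93	100	99		
MLT U1-MLT U2	D	16	63	100	91		
MLT U1-MLT U2	E	12	92	100	99		
MLT V1-MLT V2	A	14	86	65	71	specificity	recomputes to 67 under the consistency-maximising cell layout
MLT V1-MLT V2	B	11	91	99	98		printed N (10) incompatible with Sen=91; N taken as 11
MLT V1-MLT V2	C	12	92	66	73		
MLT V1-MLT V2	D	10	100	89	92		
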