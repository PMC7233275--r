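primer_pair	haplotype	n	cluster	count
MLT C1-MLT C4	A	14	1	2
MLT C1-MLT C4	A	14	2	10
MLT C1-MLT C4	A	14	4	2
MLT C1-MLT C4	B	16	1	11
MLT C1-MLT C4	B	16	3	4
MLT C1-MLT C4	B	16	5	1
MLT C1-MLT C4	C	11	1	10
MLT C1-MLT C4	C	11	2	1
MLT C1-MLT C4	D	11	1	8
MLT C1-MLT C4	D	11	2	1
MLT C1-MLT C4	D	11	3	3
MLT C3-MLT C4	A	14	1	14
MLT C3-MLT C4	B	16	1	9
MLT C3-MLT C4	B	16	2	6
MLT C3-MLT C4	B	16	3	1
MLT C3-MLT C4	C	12	1	4
MLT C3-MLT C4	C	12	2	7
MLT C3-MLT C4	C	12	4	1
MLT C3-MLT C4	D	14	1	11
MLT C3-MLT C4	D	14	2	3
MLT M1-MLT M2	A	15	2	14
MLT M1-MLT M2	A	15	3	1
MLT M1-MLT M2	B	16	1	15
MLT M1-MLT M2	B	16	4	1
MLT M1-MLT M2	C	14	2	1
MLT M1-MLT M2	C	14	3	13
MLT M1-MLT M2	D	16	1	15
MLT M1-MLT M2	D	16	4	1
MLT S1-MLT S2	A	12	3	12
MLT S1-MLT S2	B	15	1	15
MLT S1-MLT S2	C	11	4	11
MLT S1-MLT S2	D	14	2	14
MLT S1-MLT S4	A	14	1	14
MLT S1-MLT S4	B	10	4	8
MLT S1-MLT S4	B	10	5	2
MLT S1-MLT S4	C	14	1	14
MLT S1-MLT S4	D	14	3	12
MLT S1-MLT S4	D	14	7	2
MLT S1-MLT S4	E	16	2	16
MLT S1-MLT S4	F	14	6	10
MLT S1-MLT S4	F	14	8	2
MLT S1-MLT S4	F	14	9	2
MLT S3-MLT S4	A	15	2	15
MLT S3-MLT S4	B	12	4	11
MLT S3-MLT S4	B	12	7	1
MLT S3-MLT S4	C	11	5	10
MLT S3-MLT S4	C	11	6	1
MLT S3-MLT S4	D	16	1	16
MLT S3-MLT S4	E	14	3	13
MLT S3-MLT S4	E	14	9	1
MLT U1-MLT U2	A	16	1	16
MLT U1-MLT U2	B	11	3	8
MLT U1-MLT U2	B	11	6	3
MLT U1-MLT U2	C	15	2	14
MLT U1-MLT U2	C	15	11	1
MLT U1-MLT U2	D	16	4	10
MLT U1-MLT U2	D	16	5	3
MLT U1-MLT U2	D	16	8	2
MLT U1-MLT U2	D	16	9	1
MLT U1-MLT U2	E	12	7	11
MLT U1-MLT U2	E	12	10	1
MLT V1-MLT V2	A	14	1	12
MLT V1-MLT V2	A	14	2	2
MLT V1-MLT V2	B	11	2	1
MLT V1-MLT V2	B	11	3	10
MLT V1-MLT V2	C	12	1	11
MLT V1-MLT V2	C	12	2	1
MLT V1-MLT V2	D	10	2	10
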