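locus	genus	species	source_kind	accessions	forward_primer	reverse_primer	motif	repeat_count	expected_min	expected_max	outcome	n_alleles	size_min	size_max
T6	Trifolium	T. pratense	contig	gi86106666,gi86105378	CAACCAGTGGTGTGAGTAGGA	GACGTTGGTGGAGAGGTTGAG	AG	11	110	128	product	2	114	116
T7	Trifolium	T. repens	singleton	gi428283538	ATCACGCTTCACTCCTCCAC	CAACTCCAAGCTTAAGATCGTGTA	AG	13	110	122	no_product	NA	NA	NA
T1	Trifolium	T. repens	singleton	gi428292074	AGATTCCCACCAATCTCCCT	CAATACGCGGGTCTTGATCT	AG	11	210	228	stutter	NA	257	261
T2	Trifolium	T. pratense	contig	gi86106666,gi86105378	TTCCGGTTAGGTTAGGGTTT	TTTTCACATCTTCCGAAGCC	AAT	7	110	113	no_product	NA	NA	NA
T3	Trifolium	T. repens	singleton	gi428285635	CACCACATATGCAACCACAA	GTCGACGACGGTTGTTACCT	AGT	8	110	126	no_product	NA	NA	NA
T8	Trifolium	T. repens	singleton	gi428291122	GCAAAACTCAAGAGAACGGC	GGATGTCTTCGGAGGTGAGA	ACC	7	110	122	no_product	NA	NA	NA
T9	Trifolium	T. repens	singleton	gi428292435	ACAACCCATTTGCCTCAAAG	TTTTCACTTCCACCACCTCC	ACC	7	110	133	product	2	124	127
T10	Trifolium	T. pratense	singleton	gi86119186	TCCACTAGTTCTAGAGCGGC	TCCTGTAAACTGGAGGAGCC	ACC	9	110	153	no_product	NA	NA	NA
T11	Trifolium	T. pratense	singleton	gi86124411	TGGCGGTGGTGACTTATACA	TGTTTGGCAGTGGTGATGTT	AGG	8	110	153	no_product	NA	NA	NA
T4	Trifolium	T. pratense	singleton	gi86125686	GCTGCCACAGCACTACCAGA	ATATTACCGTGAATGAAGCTCAG	ACC	8	110	113	product	1	110	110
T5	Trifolium	T. pratense	singleton	gi86097190	TGAGTTCCGAGTTAAGGCTCA	TTCGGTAACTCCGAGGATTG	ACCT	5	210	217	product	2	227	230
T12	Trifolium	T. repens	singleton	gi428282514	GATTATTCAACCAAACGCCG	TAGAAAGCCACGCCAAGACT	AATCC	20	290	290	no_product	NA	NA	NA
C6	Centaurea	C. maculosa	singleton	gi124618051	TGGGATGCAGTCCAGTCATA	TTGCAACTTGCCTGTACCAC	AC	11	160	162	product	1	256	256
C1	Centaurea	C. maculosa	singleton	gi148298213	GGGAACCACACCTTTCATCT	GATCTGGCTTGACCCAAGAA	AC	10	90	119	product	2	99	101
C7	Centaurea	C. solstitialis	contig	gi124669731,gi124688599	TCGTTTTCCGATCACAAACTC	CAATTTGGCGACATCTCCTT	AC	12	110	160	product	4	114	152
C2	Centaurea	C. solstitialis	singleton	gi124680442	CGCATTATGGAATAAACCCG	GCTTTCGACTTCATAAGCGG	AAG	7	140	152	product	1	147	147
C8	Centaurea	C. maculosa	singleton	gi148296795	CGATGTATACAGGTGGTGCG	GGAGAAGGGGAGACGTAAGG	ACC	7	110	150	product	2	141	144
C9	Centaurea	C. solstitialis	singleton	gi124675484	AACGGTAGGAACCAGCATTG	GATCCTCTGGCAGGGTCATA	ACC	9	260	302	product	4	290	299
C10	Centaurea	C. solstitialis	singleton	gi124661102	AGTTGCCAGAAAGGAGCAAG	TCGAGAACAATGGCCTATCC	AGC	7	210	229	no_product	NA	NA	NA
C11	Centaurea	C. maculosa	singleton	gi148292432	TCCATGGATACAACCACCAA	GCGATATTCGGATGCAAAGT	AGG	7	160	175	product	4	160	172
C3	Centaurea	C. maculosa	singleton	gi124632630	GCCATCCCCTTCTCTACTCC	GTTACAGGTGACGATGGGG	AGT	7	160	181	no_product	NA	NA	NA
C4	Centaurea	C. solstitialis	singleton	gi124691992	CTGCACCTACCCAGAGAAGC	CGGGAGAGGGTAAATTGTGA	AGGT	5	110	115	product	3	103	109
C12	Centaurea	C. maculosa	singleton	gi124632477	ATGCATTGAGAAGGCCAATC	AACTCGCAAGCCTTTTCAAG	AATCGG	4	210	223	no_product	NA	NA	NA
C5	Centaurea	C. solstitialis	contig	gi124673348,gi124676118,gi124669484	TTAAGCATTCTTCGAGGCGT	TCTATGCCTACGCCGATCTC	AAGCAG	5	110	110	no_product	NA	NA	NA
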