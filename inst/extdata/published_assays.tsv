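assay	fwd_label	rev_label	fwd_seq	rev_seq	printed_len	mrna_fold	abc
FBXL12	143	251	ACCTGACGCTCTACACGATGC	GAGCCAGAGAACAGGTAGCCA	108	NA	NA
A_locus	-2	1063	GGATGGCCGTCATGGCGCC	CCTGGGCACTGTCACTGCTT	1065	NA	NA
B_locus	-40	1091	CACGCACCCACCCGGACTCA	TTTCAAGCTGTGAGAGACACATCA	1143	NA	NA
C_locus	-49	1073	TAAAGTCCCCAGTCACCCACC	TCAGAGCCCTGGGCACTGTT	1122	NA	NA
A*02:01:01	272	383	TGAAGGCCCACTCACAGACTC	CCCACGTCGCAGCCATACATT	111	8.9	204370
A*03:01	508	636	AAGTGGGAGGCGGCCCATGA	ATGTGTCTTGGGGGGGTCCGT	128	10.7	NA
B*07:02	522	621	CCGTGAGGCGGAGCAGCG	GTCAGCGCGCTCCAGCTTG	99	30.1	12076
B*27:02	232	337	GGGACCGGGAGACACAGATC	CGCTCTGGTTGTAGTAGCGGA	105	41.8	5174
C*02:02:02	101	218	CCGCTGTGTCCCGGCCCA	GCCCGCGGCTCCCCTCTT	117	18.6	NA
C*07:02	972	NA	TGGAGCTGTGGTCACCGCTA	NA	95	5.4	NA
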