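program	matrix	reward	penalty	gap_open	gap_extend	lambda	K	H	alpha	beta
blastn	.	1	-2	0	0	1.28	0.46	0.85	1.5	-2
blastn	.	2	-3	5	2	0.625	0.41	0.78	0.8	-2
blastn	.	2	-3	4	4	0.63	0.42	0.84	0.75	-2
blastn	.	1	-1	3	2	1.09	0.31	0.55	2	-2
blastn	.	1	-2	5	2	1.332706	0.6209911	1.124092	1.185585	0
blastn	.	4	-5	12	8	0.3010524	0.3062641	0.7531656	0.399716	0
blastp	BLOSUM62	0	0	11	1	0.267	0.041	0.14	1.9	-30
blastx	BLOSUM62	0	0	11	1	0.267	0.041	0.14	1.9	-30
tblastn	BLOSUM62	0	0	11	1	0.267	0.041	0.14	1.9	-30
tblastx	BLOSUM62	0	0	0	0	0.3176	0.134	0.4012	0.7916	-3.2
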