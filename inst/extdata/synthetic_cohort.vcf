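##fileformat=VCFv4.2
##contig=<ID=Y>
##source=synthetic toy cohort for haploid VCF ingest tests
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s01	s02	s03	s04	s05	s06	s07	s08	s09
Y	101	.	A	G	.	PASS	.	GT	0	0	1	0	0	0	0	0	0
Y	250	.	C	T	.	PASS	.	GT	0/0	0/0	0/0	1/1	1/1	0/0	0/0	0/0	0/0
Y	333	.	G	A	.	PASS	.	GT	0	1	1	1	1	1	0	0	.
Y	471	.	T	C	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	1|1	0|0	0|0
Y	502	.	A	T	.	PASS	.	GT	0	0	0	0	0/1	0	0	1	1
Y	640	.	G	C,T	.	PASS	.	GT	0	0	0	1	1	2	0	0	0
Y	777	.	C	G	.	PASS	.	GT	0	0	0	0	0	0	0	0	0
Y	905	.	T	A	.	PASS	.	GT	1	1	1	1	1	1	1	1	1
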