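##fileformat=VCFv4.2
##source=pbiScan-simulator
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s00001	s00002	s00003	s00004	s00005	s00006	s00007	s00008	s00009	s00010	s00011	s00012
3	1000	snp00001	A	B	.	PASS	.	GT	0/1	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/0	0/1	0/0	0/0
3	2000	snp00002	A	B	.	PASS	.	GT	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/1	1/1	0/0
3	3000	snp00003	A	B	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/0	1/1	1/1	0/1	0/0	0/1	1/1
3	4000	snp00004	A	B	.	PASS	.	GT	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	1/1	0/1
3	5000	snp00005	A	B	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0	1/1	0/0	0/1	0/1	0/0	0/1
3	6000	snp00006	A	B	.	PASS	.	GT	0/0	0/1	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/1	1/1	0/0
3	7000	snp00007	A	B	.	PASS	.	GT	0/0	0/0	0/0	1/1	0/1	1/1	0/1	0/1	0/1	0/0	0/1	0/0
3	8000	snp00008	A	B	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	1/1	0/0
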