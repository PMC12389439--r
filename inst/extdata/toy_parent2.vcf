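##fileformat=VCFv4.2
##source=bsapilla-toy
##contig=<ID=chr1,length=1000>
##contig=<ID=chr2,length=1000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	P2
chr1	100	.	A	G	.	PASS	.	GT:AD	1/1:0,15
chr1	200	.	A	G,T	.	PASS	.	GT:AD	1/1:0,15
chr1	300	.	A	AT	.	PASS	.	GT:AD	1/1:0,15
chr1	400	.	A	G	.	PASS	.	GT:AD	1/1:0,15
chr2	150	.	A	G	.	PASS	.	GT:AD	0/0:15,0
chr2	250	.	A	G	.	PASS	.	GT:AD	0/0:15,0
chr2	350	.	AT	A	.	PASS	.	GT:AD	1/1:0,15
chr2	450	.	A	G	.	PASS	.	GT:AD	1/1:0,15
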