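##fileformat=VCFv4.2
##contig=<ID=1,length=249250621>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	sampleA	sampleB	sampleC
1	1000	rs1	A	G	.	PASS	.	GT	0/0	0/1	1/1
1	2000	rs2	C	T	.	PASS	.	GT	0|1	1|1	0/0
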