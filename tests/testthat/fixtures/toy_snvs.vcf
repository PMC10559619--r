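##fileformat=VCFv4.2
##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID'">
##contig=<ID=chr5>
##contig=<ID=chr11>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr5	1001	.	C	A	60	PASS	ANN=A|missense_variant|MODERATE|Kit|ENSMUSG0001
chr11	2050	.	G	T	60	PASS	ANN=T|stop_gained|HIGH|Rara|ENSMUSG0002
chr11	30001	.	T	C	60	PASS	DP=40
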