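##fileformat=VCFv4.3
##INFO=<ID=TCN,Number=1,Type=Integer,Description="Total depth">
##INFO=<ID=ACN,Number=1,Type=Integer,Description="Alt depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	100	.	A	G	50	PASS	TCN=60;ACN=30
chr1	200	.	C	T	40	PASS	TCN=80;ACN=20
chr2	300	.	G	C	45	PASS	TCN=50;ACN=25
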