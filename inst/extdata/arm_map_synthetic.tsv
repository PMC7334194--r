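chrom	arm	start	end
chr1	p	0	120000000
chr1	q	125000000	245000000
chr2	p	0	90000000
chr2	q	95000000	190000000
chr3	p	0	60000000
chr3	q	65000000	160000000
chr4	p	0	50000000
chr4	q	55000000	140000000
chr5	p	0	45000000
chr5	q	48000000	120000000
chr6	p	0	35000000
chr6	q	38000000	100000000
chr7	p	0	25000000
chr7	q	28000000	85000000
chr8	p	0	20000000
chr8	q	23000000	70000000
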