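fixedStep chrom=chr1 start=1 step=20 span=20
1
2
5
9
12
9
5
2
1
1
fixedStep chrom=chr1 start=101 step=10 span=10
2
4
8
16
8
4
2
1
1
1
1
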