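chr1	1918	2082	macs_like_1	0.77
chr1	3135	3458	macs_like_2	5.23
chr1	8021	8368	macs_like_3	4.24
chr1	10695	11056	macs_like_4	1.97
chr1	16955	17097	macs_like_5	2.11
chr1	24318	24547	macs_like_6	8.77
chr1	25889	26036	macs_like_7	1.66
chr1	27741	28074	macs_like_8	7.96
chr1	31618	31846	macs_like_9	7.73
chr1	32933	33301	macs_like_10	4.33
chr1	44554	44929	macs_like_11	3.47
chr1	48152	48536	macs_like_12	4.7
chr1	49479	49778	macs_like_13	5.14
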