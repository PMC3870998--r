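chr1	3127	3476	cisgenome_like_1	47.7
chr1	7993	8362	cisgenome_like_2	25.17
chr1	8806	8980	cisgenome_like_3	29.54
chr1	16959	17124	cisgenome_like_4	27.09
chr1	24289	24587	cisgenome_like_5	32.32
chr1	25880	26042	cisgenome_like_6	26.41
chr1	27738	28073	cisgenome_like_7	41.51
chr1	31631	31838	cisgenome_like_8	10.1
chr1	32920	33336	cisgenome_like_9	19.15
chr1	44573	44944	cisgenome_like_10	32.92
chr1	49489	49763	cisgenome_like_11	34.36
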