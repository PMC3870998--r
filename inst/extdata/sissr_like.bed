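chr1	3117	3461	sissr_like_1	287.77
chr1	8004	8357	sissr_like_2	83.77
chr1	16960	17133	sissr_like_3	874.5
chr1	24276	24578	sissr_like_4	264.23
chr1	25900	26038	sissr_like_5	272.78
chr1	27721	28083	sissr_like_6	440.86
chr1	28232	28406	sissr_like_7	19.62
chr1	31635	31841	sissr_like_8	837.97
chr1	44559	44904	sissr_like_9	421.3
chr1	46390	46751	sissr_like_10	321.05
chr1	49505	49761	sissr_like_11	328.46
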