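chr1	3128	3459	TP
chr1	7996	8371	TP
chr1	16957	17121	TP
chr1	24296	24571	TP
chr1	25877	26051	TP
chr1	27721	28082	TP
chr1	29548	29772	TP
chr1	31626	31860	TP
chr1	32938	33315	TP
chr1	44573	44924	TP
chr1	48152	48530	TP
chr1	49487	49759	TP
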