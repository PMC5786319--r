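receptor	condition	n_trajectories	total_length_us
D2R	WT	37	18.0
D2R	E2.65A	37	21.3
D3R	WT	36	21.3
D3R	E2.65A	35	15.9
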