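block_index	trial_index	stimulus_id	correct_mapping	applied_mapping	rule_correct	feedback	feedback_valid	instruction	phase
1	1	b01_s1	A	A	TRUE	positive	TRUE	volatility	pre_reversal
1	2	b01_s2	A	B	FALSE	negative	TRUE	volatility	pre_reversal
1	3	b01_s1	A	A	TRUE	negative	FALSE	volatility	pre_reversal
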