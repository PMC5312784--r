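# Volatility-instruction design, short response-feedback interval.
experiment_id: exp1a
n_blocks: 36
block_lengths: [25, 33, 41]
response_feedback_interval: 500
instruction_reversal_prob:
  volatility: 0.6666666666666666
  stability: 0.3333333333333333
reliability_levels:
  standard: 0.75
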