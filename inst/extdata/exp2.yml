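# Reliability-instruction design: three objective feedback reliabilities,
# reversals in 3/4 of the blocks at trial 9, 17 or 25.
experiment_id: exp2
n_blocks: 32
block_lengths: [33]
response_feedback_interval: 500
instruction_reversal_prob:
  reliable_instructed: 0.75
  unreliable_instructed: 0.75
reliability_levels:
  high: 0.875
  intermediate: 0.75
  low: 0.625
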