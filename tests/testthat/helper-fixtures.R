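# Shared fixture builders for the test suite.

# Minimal valid trial log; every argument overrides a column.
toyLog <- function(applied, feedback,
                   rule_correct = rep(TRUE, length(applied)),
                   instruction = rep("volatility", length(applied)),
                   phase = rep("pre_reversal", length(applied)),
                   correct_mapping = rep("A", length(applied)),
                   block_index = rep(1L, length(applied)),
                   subject_id = rep("s01", length(applied))) {
  n <- length(applied)
  data.frame(
    block_index = block_index,
    trial_index = stats::ave(seq_len(n), block_index, FUN = seq_along),
    stimulus_id = rep("stim", n),
    correct_mapping = correct_mapping,
    applied_mapping = applied,
    rule_correct = rule_correct,
    feedback = feedback,
    feedback_valid = (feedback == "positive") == rule_correct,
    instruction = instruction,
    phase = phase,
    subject_id = subject_id)
}

# One-row block description accepted by runBlock().
toyBlock <- function(length = 33L, instruction = "volatility",
                     reliability = 0.75, has_reversal = TRUE,
                     reversal_trial = if (has_reversal) (length + 1L) %/% 2L
                                      else NA_integer_,
                     initial_mapping = "A", index = 1L) {
  list(index = index, instruction = instruction, length = length,
       reliability = reliability, has_reversal = has_reversal,
       reversal_trial = reversal_trial, stim1 = "s1", stim2 = "s2",
       initial_mapping = initial_mapping)
}

# Flat-signal EpochSet on the standard montage.
flatEpochs <- function(n_trials = 2, value = 0, fs = 250,
                       window = c(-500, 1500), trialInfo = NULL) {
  times <- seq(window[1], window[2], by = 1000 / fs)
  mont <- standardMontage()
  EpochSet(array(value, c(length(mont), length(times), n_trials)),
           samplingRate = fs, times = times, channelNames = mont,
           trialInfo = trialInfo)
}

# Brute-force two-state HMM filter by explicit path enumeration; the
# independent oracle for the recursive belief. States: 1 = the mapping
# applied on that trial is objectively correct, 0 = it is not. Returns the
# posterior that the final trial's applied mapping is correct.
enumerateBelief <- function(applied, feedback, h, rho) {
  n <- length(applied)
  total <- 0
  hit <- 0
  # state coded relative to mapping "A"; s = 1 means A is correct
  for (bits in 0:(2^n - 1)) {
    s <- as.integer(intToBits(bits))[seq_len(n)]
    w <- 0.5
    for (t in seq_len(n)) {
      if (t > 1) w <- w * (if (s[t] == s[t - 1]) 1 - h else h)
      correct_applied <- (applied[t] == "A") == (s[t] == 1)
      p_pos <- if (correct_applied) rho else 1 - rho
      w <- w * (if (feedback[t] == "positive") p_pos else 1 - p_pos)
    }
    total <- total + w
    final_correct <- (applied[n] == "A") == (s[n] == 1)
    if (final_correct) hit <- hit + w
  }
  hit / total
}
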