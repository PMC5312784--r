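#' Experiment configuration for the instructed reversal-learning task
#'
#' Returns the design parameters of the three supported experiment layouts.
#' Experiments 1a and 1b manipulate instructed volatility ("the rules in this
#' block will probably change / remain stable") with reversals in 2/3 of
#' volatility-instructed and 1/3 of stability-instructed blocks, block lengths
#' 25/33/41 and a reversal at the block midpoint. Experiment 2 manipulates
#' instructed feedback reliability with three objective reliability levels
#' (0.875 / 0.75 / 0.625), 32 blocks of 33 trials, a reversal in 3/4 of the
#' blocks located equally often at trial 9, 17 or 25.
#'
#' @param experiment_id One of `"exp1a"`, `"exp1b"`, `"exp2"`.
#' @return An object of class `experiment_config`: a list with fields
#'   `experiment_id`, `n_blocks`, `block_lengths`,
#'   `response_feedback_interval` (ms), `instruction_reversal_prob` (named
#'   probability per instruction), `reliability_levels`, and `instructions`.
#' @export
experimentConfig <- function(experiment_id = c("exp1a", "exp1b", "exp2")) {
  experiment_id <- match.arg(experiment_id)
  cfg <- switch(experiment_id,
    exp1a = list(
      experiment_id = "exp1a",
      n_blocks = 36L,
      block_lengths = c(25L, 33L, 41L),
      response_feedback_interval = 500,
      instruction_reversal_prob = c(volatility = 2 / 3, stability = 1 / 3),
      reliability_levels = c(standard = 0.75),
      instructions = c("volatility", "stability")
    ),
    exp1b = list(
      experiment_id = "exp1b",
      n_blocks = 27L,
      block_lengths = c(25L, 33L, 41L),
      response_feedback_interval = 1200,
      instruction_reversal_prob = c(volatility = 2 / 3, stability = 1 / 3),
      reliability_levels = c(standard = 0.75),
      instructions = c("volatility", "stability")
    ),
    exp2 = list(
      experiment_id = "exp2",
      n_blocks = 32L,
      block_lengths = 33L,
      response_feedback_interval = 500,
      instruction_reversal_prob = c(reliable_instructed = 3 / 4,
                                    unreliable_instructed = 3 / 4),
      reliability_levels = c(high = 0.875, intermediate = 0.75, low = 0.625),
      instructions = c("reliable_instructed", "unreliable_instructed")
    )
  )
  validateExperimentConfig(cfg)
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from a structured-text file
#'
#' Configurations are plain YAML key/value files mirroring the
#' [experimentConfig()] fields; defaults for the three experiment layouts
#' ship with the package under `extdata` (`exp1a.yml`, `exp1b.yml`,
#' `exp2.yml`).
#'
#' @param path Path to a YAML configuration file.
#' @return An `experiment_config` object.
#' @examples
#' cfg <- readExperimentConfig(
#'   system.file("extdata", "exp1a.yml", package = "RevLearnEEG"))
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  needed <- c("experiment_id", "n_blocks", "block_lengths",
              "response_feedback_interval", "instruction_reversal_prob",
              "reliability_levels")
  missing_fields <- setdiff(needed, names(raw))
  if (length(missing_fields) > 0)
    stop("configuration is missing fields: ",
         paste(missing_fields, collapse = ", "))
  cfg <- list(
    experiment_id = raw$experiment_id,
    n_blocks = as.integer(raw$n_blocks),
    block_lengths = as.integer(unlist(raw$block_lengths)),
    response_feedback_interval = raw$response_feedback_interval,
    instruction_reversal_prob = unlist(raw$instruction_reversal_prob),
    reliability_levels = unlist(raw$reliability_levels),
    instructions = names(unlist(raw$instruction_reversal_prob)))
  validateExperimentConfig(cfg)
  class(cfg) <- "experiment_config"
  cfg
}

validateExperimentConfig <- function(cfg) {
  p <- cfg$instruction_reversal_prob
  if (any(p < 0 | p > 1)) stop("reversal probabilities must lie in [0, 1]")
  if (any(cfg$reliability_levels < 0 | cfg$reliability_levels > 1))
    stop("reliability levels must lie in [0, 1]")
  if (any(cfg$block_lengths %% 2L != 1L))
    stop("block lengths must be odd so the midpoint trial is defined")
  invisible(cfg)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration:", x$experiment_id, "\n")
  cat("  blocks:", x$n_blocks, " lengths:",
      paste(x$block_lengths, collapse = "/"), "\n")
  cat("  reversal probability:",
      paste(sprintf("%s=%.3f", names(x$instruction_reversal_prob),
                    x$instruction_reversal_prob), collapse = ", "), "\n")
  cat("  feedback reliability:",
      paste(sprintf("%s=%.3f", names(x$reliability_levels),
                    x$reliability_levels), collapse = ", "), "\n")
  invisible(x)
}

## Largest-remainder allocation of `total` items over cells with the given
## target weights; remainders are assigned in seeded random order so a
## schedule that cannot be crossed exactly is still reproducible.
allocateCounts <- function(total, weights) {
  ideal <- total * weights / sum(weights)
  base <- floor(ideal)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- ideal - base
    order_idx <- sample(seq_along(weights))   # seeded tie-break
    pick <- order_idx[order(-frac[order_idx])][seq_len(rem)]
    base[pick] <- base[pick] + 1
  }
  as.integer(base)
}

#' Build a counterbalanced block schedule
#'
#' Constructs the full block list for an experiment: instruction, length,
#' objective feedback reliability, reversal status and reversal trial, with
#' exact counterbalancing of instruction x length x reversal status wherever
#' the design divides evenly (it does for exp1a and exp2). The block order is
#' shuffled by `seed`. Each block receives a fresh stimulus pair and a random
#' initial correct mapping.
#'
#' For exp1a, 12 of the 18 volatility-instructed blocks and 6 of the 18
#' stability-instructed blocks contain a reversal, exactly, with lengths
#' balanced within every cell. For exp2, each of the four block types
#' (0.875-reliable instructed-reliable, 0.625 instructed-unreliable, and the
#' two 0.75 types under either instruction) appears 8 times with exactly 6
#' reversal blocks, whose reversal trials are 9/17/25 twice each. exp1b has
#' 27 blocks, which a 2 x 3 x thirds design cannot cross exactly; cell counts
#' are then assigned by largest-remainder allocation under `seed`.
#'
#' @param config An [experimentConfig()] object.
#' @param seed Integer master seed for the schedule stream.
#' @param exact Require exact counterbalancing (error if the counts do not
#'   divide). Defaults to `TRUE` except for exp1b.
#' @return A data frame of class `block_schedule`, one row per block, columns
#'   `index`, `instruction`, `length`, `reliability`, `has_reversal`,
#'   `reversal_trial` (`NA` when no reversal), `stim1`, `stim2`,
#'   `initial_mapping`.
#' @export
buildSchedule <- function(config, seed = 1L,
                          exact = config$experiment_id != "exp1b") {
  validateExperimentConfig(config)
  set.seed(deriveSeed(seed, "schedule"))
  rows <- if (config$experiment_id == "exp2") {
    scheduleCellsExp2(config, exact)
  } else {
    scheduleCellsExp1(config, exact)
  }
  rows <- rows[sample(nrow(rows)), , drop = FALSE]
  rows$index <- seq_len(nrow(rows))
  rows$stim1 <- sprintf("b%02d_s1", rows$index)
  rows$stim2 <- sprintf("b%02d_s2", rows$index)
  rows$initial_mapping <- sample(c("A", "B"), nrow(rows), replace = TRUE)
  rownames(rows) <- NULL
  rows <- rows[, c("index", "instruction", "length", "reliability",
                   "has_reversal", "reversal_trial", "stim1", "stim2",
                   "initial_mapping")]
  class(rows) <- c("block_schedule", "data.frame")
  rows
}

scheduleCellsExp1 <- function(config, exact) {
  instr <- config$instructions
  n_instr <- length(instr)
  lengths <- config$block_lengths
  rho <- unname(config$reliability_levels[1])
  per_instr <- config$n_blocks / n_instr
  rows <- list()
  if (exact) {
    for (ins in instr) {
      p_rev <- config$instruction_reversal_prob[[ins]]
      per_len <- per_instr / length(lengths)
      for (len in lengths) {
        n_rev <- p_rev * per_len
        if (!isWhole(per_len) || !isWhole(n_rev))
          stop(sprintf(
            "counterbalancing does not divide in cell instruction '%s' x length %d",
            ins, len))
        per_len <- round(per_len)
        n_rev <- round(n_rev)
        rows[[length(rows) + 1L]] <- data.frame(
          instruction = ins, length = len, reliability = rho,
          has_reversal = rep(c(TRUE, FALSE), c(n_rev, per_len - n_rev)))
      }
    }
  } else {
    n_by_instr <- allocateCounts(config$n_blocks, rep(1, n_instr))
    for (i in seq_along(instr)) {
      ins <- instr[i]
      p_rev <- config$instruction_reversal_prob[[ins]]
      n_len <- allocateCounts(n_by_instr[i], rep(1, length(lengths)))
      n_rev_total <- round(p_rev * n_by_instr[i])
      n_rev_by_len <- allocateCounts(n_rev_total, pmax(n_len, 1e-9))
      for (j in seq_along(lengths)) {
        if (n_len[j] == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          instruction = ins, length = lengths[j], reliability = rho,
          has_reversal = rep(c(TRUE, FALSE),
                             c(n_rev_by_len[j], n_len[j] - n_rev_by_len[j])))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$reversal_trial <- ifelse(out$has_reversal, (out$length + 1L) %/% 2L,
                               NA_integer_)
  out
}

scheduleCellsExp2 <- function(config, exact) {
  len <- config$block_lengths[1]
  types <- data.frame(
    instruction = c("reliable_instructed", "unreliable_instructed",
                    "reliable_instructed", "unreliable_instructed"),
    reliability = c(0.875, 0.625, 0.75, 0.75)
  )
  n_per_type <- config$n_blocks / nrow(types)
  p_rev <- config$instruction_reversal_prob[[1]]
  n_rev <- p_rev * n_per_type
  if (exact && (!isWhole(n_per_type) || !isWhole(n_rev) ||
                !isWhole(n_rev / 3)))
    stop("counterbalancing does not divide in the exp2 reliability x reversal cells")
  n_per_type <- round(n_per_type)
  n_rev <- round(n_rev)
  rows <- list()
  for (k in seq_len(nrow(types))) {
    rev_trials <- rep(c(9L, 17L, 25L), each = n_rev / 3)
    rows[[k]] <- data.frame(
      instruction = types$instruction[k], length = len,
      reliability = types$reliability[k],
      has_reversal = rep(c(TRUE, FALSE), c(n_rev, n_per_type - n_rev)),
      reversal_trial = c(rev_trials, rep(NA_integer_, n_per_type - n_rev)))
  }
  do.call(rbind, rows)
}

#' Reversal trial for a block
#'
#' Experiment 1 reverses deterministically at the block midpoint
#' ((length + 1) / 2, i.e. trial 13, 17 or 21 for lengths 25, 33, 41).
#' Experiment 2 draws uniformly from trials 9, 17, 25; at schedule level
#' [buildSchedule()] enforces exactly equal counts instead of sampling.
#'
#' @param length Block length in trials.
#' @param experiment_id `"exp1a"`, `"exp1b"` or `"exp2"`.
#' @return Integer 1-based trial index of the first trial governed by the
#'   reversed rule.
#' @export
reversalTrialFor <- function(length, experiment_id) {
  if (experiment_id %in% c("exp1a", "exp1b")) {
    if (!length %in% c(25L, 33L, 41L))
      stop("unsupported block length for experiment 1: ", length)
    as.integer((length + 1L) %/% 2L)
  } else if (experiment_id == "exp2") {
    if (length != 33L) stop("unsupported block length for experiment 2: ", length)
    sample(c(9L, 17L, 25L), 1L)
  } else {
    stop("unknown experiment_id: ", experiment_id)
  }
}

#' Draw probabilistic feedback
#'
#' Feedback valence matches the rule-correctness of the response with
#' probability `rho`, independently per trial: a rule-correct response draws
#' positive feedback with probability `rho` and (invalid) negative feedback
#' otherwise, and conversely for rule-incorrect responses.
#'
#' @param rule_correct Logical vector, one element per trial.
#' @param rho Feedback reliability in `[0, 1]`.
#' @return Data frame with columns `feedback` (`"positive"`/`"negative"`) and
#'   `valid` (logical: valence matched rule-correctness).
#' @export
drawFeedback <- function(rule_correct, rho) {
  stopifnot(rho >= 0, rho <= 1, is.logical(rule_correct))
  valid <- stats::runif(length(rule_correct)) < rho
  positive <- rule_correct == valid
  data.frame(feedback = ifelse(positive, "positive", "negative"),
             valid = valid)
}

## Stimulus sequence for one block: each of the two stimuli appears on
## ceiling(length/2) or floor(length/2) trials, order seeded pseudo-random.
stimulusSequence <- function(block) {
  n1 <- ceiling(block$length / 2)
  sample(rep(c(block$stim1, block$stim2), c(n1, block$length - n1)))
}

## Phase boundary: the reversal trial itself is the first post-reversal
## trial; blocks without a reversal use the nominal midpoint so matched-trial
## comparisons between reversal and non-reversal blocks use equal halves.
phaseBoundary <- function(block) {
  if (isTRUE(block$has_reversal)) block$reversal_trial
  else (block$length + 1L) %/% 2L
}

#' Run one block of the task with an agent
#'
#' Plays a single block trial by trial: the correct stimulus-response mapping
#' starts at the block's `initial_mapping`, flips once at `reversal_trial`
#' (and never again), stimuli alternate pseudo-randomly with both stimuli
#' occurring on half the trials, and feedback follows [drawFeedback()] at the
#' block's reliability. The feedback-validity draws and the agent's internal
#' randomness use independent sub-streams of `seed`, so two agents run on the
#' same block and seed experience the same validity sequence.
#'
#' @param block One row of a [buildSchedule()] data frame (or an equivalent
#'   list).
#' @param agent An agent object (see [hmmAgent()], [oracleAgent()]): a list
#'   with functions `reset(block)`, `act(stimulus, correct_mapping)`,
#'   `observe(feedback)` and optionally `trace()` returning extra per-trial
#'   log columns.
#' @param seed Integer seed.
#' @return Data frame with one row per trial: `block_index`, `trial_index`,
#'   `instruction`, `stimulus_id`, `correct_mapping`, `applied_mapping`,
#'   `rule_correct`, `feedback`, `feedback_valid`, `phase`, plus any columns
#'   emitted by `agent$trace()`.
#' @export
runBlock <- function(block, agent, seed = 1L) {
  block <- as.list(block)
  len <- block$length
  set.seed(deriveSeed(seed, "feedback"))
  valid_draw <- stats::runif(len)
  set.seed(deriveSeed(seed, "agent"))
  stim <- stimulusSequence(block)
  boundary <- phaseBoundary(block)
  agent$reset(block)
  correct0 <- block$initial_mapping
  has_trace <- is.function(agent$trace)
  applied <- correct_mapping <- feedback <- character(len)
  rule_correct <- logical(len)
  trace_rows <- if (has_trace) vector("list", len)
  for (t in seq_len(len)) {
    reversed <- isTRUE(block$has_reversal) && t >= block$reversal_trial
    correct_mapping[t] <- if (reversed) otherMapping(correct0) else correct0
    applied[t] <- agent$act(stim[t], correct_mapping[t])
    rule_correct[t] <- applied[t] == correct_mapping[t]
    valid <- valid_draw[t] < block$reliability
    feedback[t] <- if (rule_correct[t] == valid) "positive" else "negative"
    agent$observe(feedback[t])
    if (has_trace) trace_rows[[t]] <- agent$trace()
  }
  out <- data.frame(
    block_index = block$index %||% 1L, trial_index = seq_len(len),
    instruction = block$instruction, stimulus_id = stim,
    correct_mapping = correct_mapping, applied_mapping = applied,
    rule_correct = rule_correct, feedback = feedback,
    feedback_valid = valid_draw < block$reliability,
    phase = ifelse(seq_len(len) >= boundary, "post_reversal", "pre_reversal"))
  if (has_trace)
    out <- cbind(out, as.data.frame(do.call(rbind, trace_rows)))
  out
}

trialLogColumns <- function() {
  c("block_index", "trial_index", "stimulus_id", "correct_mapping",
    "applied_mapping", "rule_correct", "feedback", "feedback_valid",
    "instruction", "phase")
}

#' Write / read a tab-delimited trial log
#'
#' The on-disk trial log is plain tab-delimited text with a header row and
#' 1-based trial indices; all columns of the in-memory log (including agent
#' trace columns such as `p`, `H`, `I` and `subject_id`) round-trip
#' losslessly.
#'
#' @param trials Trial-log data frame (from [runBlock()],
#'   [simulateSubject()], ...).
#' @param path File path.
#' @return `writeTrialLog()` returns `path` invisibly; `readTrialLog()`
#'   returns the trial-log data frame.
#' @export
writeTrialLog <- function(trials, path) {
  missing_cols <- setdiff(trialLogColumns(), names(trials))
  if (length(missing_cols) > 0)
    stop("trial log is missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialLog
#' @export
readTrialLog <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2) stop("trial log has no data rows: ", path)
  bad <- which(nf != nf[1])
  if (length(bad) > 0)
    stop(sprintf("malformed trial log row at line %d of %s", bad[1], path))
  log <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trialLogColumns(), names(log))
  if (length(missing_cols) > 0)
    stop("trial log is missing columns: ", paste(missing_cols, collapse = ", "))
  log$rule_correct <- as.logical(log$rule_correct)
  log$feedback_valid <- as.logical(log$feedback_valid)
  log
}
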