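#' Binary entropy in bits
#'
#' `H(p) = -p log2 p - (1 - p) log2(1 - p)` with `0 log 0 = 0`; symmetric in
#' `p` and `1 - p`, maximal (1 bit) at `p = 0.5`.
#'
#' @param p Probability (vectorised).
#' @return Entropy in bits, in `[0, 1]`.
#' @export
binaryEntropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Hidden-state transition of the belief
#'
#' One step of the two-state Markov chain with per-trial reversal hazard `h`:
#' the belief that the current mapping is correct contracts toward 0.5,
#' `p' = p (1 - h) + (1 - p) h`.
#'
#' @param p Belief probability.
#' @param h Hazard in `[0, 0.5]`.
#' @return Updated probability.
#' @export
transitionBelief <- function(p, h) {
  stopifnot(all(p >= 0 & p <= 1), all(h >= 0 & h <= 0.5))
  p * (1 - h) + (1 - p) * h
}

#' Bayesian belief update from one feedback event
#'
#' Integrates one feedback valence with the prior that the implemented
#' mapping is correct, under assumed feedback reliability `rho`
#' (`P(positive | correct) = P(negative | incorrect) = rho`). Also returns
#' the surprise of the outcome, `I = -log2` of its predictive probability,
#' and the entropy `H` of the posterior.
#'
#' @param p Prior probability that the implemented mapping is correct.
#' @param feedback `"positive"` or `"negative"`.
#' @param rho Assumed feedback reliability.
#' @return List with elements `p` (posterior), `I` (surprise, bits), `H`
#'   (posterior entropy, bits).
#' @export
updateBelief <- function(p, feedback, rho) {
  stopifnot(p >= 0, p <= 1, rho >= 0, rho <= 1,
            feedback %in% c("positive", "negative"))
  L <- if (feedback == "positive") rho else 1 - rho
  pred <- p * L + (1 - p) * (1 - L)
  if (pred == 0)
    stop("feedback has predictive probability 0 under this belief")
  p_post <- p * L / pred
  list(p = p_post, I = -log2(pred), H = binaryEntropy(p_post))
}

#' Entropy-aversion switch rule
#'
#' The observer abandons its current mapping when it both believes the
#' mapping is more likely wrong than right (`p < 0.5`) and its uncertainty
#' has fallen to at most the entropy-aversion threshold (`H(p) <= alpha`).
#' Larger `alpha` therefore produces earlier switching; `alpha` in bits,
#' `[0, 1]`.
#'
#' @param belief List with elements `p` and `H` (see [updateBelief()]).
#' @param alpha Entropy-aversion threshold in bits.
#' @param current_mapping `"A"` or `"B"`.
#' @return The mapping to apply on the next trial.
#' @export
decideMapping <- function(belief, alpha, current_mapping) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (belief$p < 0.5 && belief$H <= alpha) otherMapping(current_mapping)
  else current_mapping
}

#' One Rescorla-Wagner update
#'
#' `delta = reward - q`; `q' = q + eta * delta`. Rewards are coded 1
#' (positive feedback) and 0 (negative feedback).
#'
#' @param q Current value estimate in `[0, 1]`.
#' @param reward 0 or 1.
#' @param eta Learning rate in `[0, 1]`.
#' @return List with `delta` (signed reward prediction error) and `q`
#'   (updated value).
#' @export
rlStep <- function(q, reward, eta) {
  stopifnot(q >= 0, q <= 1, reward %in% c(0, 1), eta >= 0, eta <= 1)
  delta <- reward - q
  list(delta = delta, q = q + eta * delta)
}

#' Agent parameter set
#'
#' @param alpha Entropy-aversion threshold(s) in bits. A single unnamed value
#'   for the instruction-blind observer, or a named vector with one value per
#'   instruction (e.g. `c(volatility = 0.7, stability = 0.52)`) for the
#'   instruction-sensitive observer.
#' @param h Per-trial reversal hazard; default 0.03 (about one reversal per
#'   33 trials).
#' @param rho Assumed feedback reliability; default 0.75, the contingency of
#'   the experiment-1 design and the exp2 target blocks.
#' @param eta Learning rate of the model-free learner; default 0.5.
#' @param epsilon Response lapse rate in `[0, 0.5]`: probability that the
#'   applied mapping is the opposite of the intended one.
#' @return List of class `agent_params`.
#' @export
agentParams <- function(alpha = 0.6, h = 0.03, rho = 0.75, eta = 0.5,
                        epsilon = 0) {
  stopifnot(all(alpha >= 0 & alpha <= 1), h >= 0, h <= 0.5,
            rho > 0, rho <= 1, eta >= 0, eta <= 1,
            epsilon >= 0, epsilon <= 0.5)
  structure(list(alpha = alpha, h = h, rho = rho, eta = eta,
                 epsilon = epsilon),
            class = "agent_params")
}

#' Bayesian hidden-Markov observer agent
#'
#' A two-state hidden-Markov observer over "my current mapping is correct"
#' vs. "it is not". The belief starts at 0.5 in every block, undergoes the
#' hazard transition before each response, is updated by Bayes after each
#' feedback, and the mapping is switched by the entropy-aversion rule of
#' [decideMapping()]. The instruction-blind variant uses one `alpha` for all
#' blocks; the instruction-sensitive variant selects `alpha` by the block's
#' instruction and has exactly one extra free parameter per additional
#' instruction. Responses lapse (flip) with probability `epsilon`; after a
#' lapse the belief refers to the mapping actually applied.
#'
#' Per trial the agent logs `p` (posterior that the applied mapping is
#' correct), `H` (posterior entropy, bits) and `I` (outcome surprise, bits).
#'
#' @param params An [agentParams()] object.
#' @param variant `"blind"` or `"instruction_sensitive"`.
#' @return An agent object usable with [runBlock()].
#' @export
hmmAgent <- function(params, variant = c("blind", "instruction_sensitive")) {
  variant <- match.arg(variant)
  if (variant == "instruction_sensitive" && is.null(names(params$alpha)))
    stop("instruction-sensitive variant needs a named alpha per instruction")
  e <- new.env(parent = emptyenv())
  reset <- function(block) {
    e$p <- 0.5
    e$current <- sample(c("A", "B"), 1L)
    e$alpha <- if (variant == "blind") unname(params$alpha[1]) else {
      a <- unname(params$alpha[block$instruction])
      if (is.na(a)) stop("no alpha for instruction: ", block$instruction)
      a
    }
    e$lastP <- NA_real_; e$lastH <- NA_real_; e$lastI <- NA_real_
  }
  act <- function(stimulus, correct_mapping) {
    e$p <- transitionBelief(e$p, params$h)
    applied <- e$current
    if (params$epsilon > 0 && stats::runif(1) < params$epsilon)
      applied <- otherMapping(applied)
    if (applied != e$current) {       # lapse: re-reference belief
      e$p <- 1 - e$p
      e$current <- applied
    }
    applied
  }
  observe <- function(feedback) {
    up <- updateBelief(e$p, feedback, params$rho)
    e$p <- up$p
    e$lastP <- up$p; e$lastH <- up$H; e$lastI <- up$I
    nxt <- decideMapping(up, e$alpha, e$current)
    if (nxt != e$current) {
      e$p <- 1 - e$p
      e$current <- nxt
    }
  }
  trace <- function() c(p = e$lastP, H = e$lastH, I = e$lastI)
  list(reset = reset, act = act, observe = observe, trace = trace,
       variant = variant, params = params)
}

#' Oracle agent
#'
#' Always applies the currently correct mapping; useful for measuring raw
#' feedback contingencies (e.g. the negative-feedback rate on rule-correct
#' trials).
#'
#' @return An agent object usable with [runBlock()].
#' @export
oracleAgent <- function() {
  list(reset = function(block) invisible(NULL),
       act = function(stimulus, correct_mapping) correct_mapping,
       observe = function(feedback) invisible(NULL),
       trace = NULL)
}

#' Simulate one subject through a full experiment
#'
#' Builds the counterbalanced schedule for `config`, then runs the
#' hidden-Markov observer through every block. Belief and mapping are reset
#' at each block start (each block brings new stimuli). Schedule, feedback
#' and agent randomness use independent sub-streams of `seed`.
#'
#' @param config [experimentConfig()] object.
#' @param params [agentParams()]; for the instruction-sensitive variant
#'   `alpha` must be named by instruction.
#' @param variant `"blind"` or `"instruction_sensitive"`.
#' @param seed Integer seed.
#' @param subject_id Label stored in the `subject_id` column.
#' @return Trial-log data frame (one row per trial) with the standard task
#'   columns plus `subject_id`, `p`, `H`, `I`.
#' @export
simulateSubject <- function(config, params, variant = "blind", seed = 1L,
                            subject_id = "s01") {
  schedule <- buildSchedule(config, seed = deriveSeed(seed, "schedule-sub"))
  agent <- hmmAgent(params, variant)
  logs <- lapply(seq_len(nrow(schedule)), function(b) {
    runBlock(schedule[b, ], agent,
             seed = deriveSeed(seed, paste0("block", b)))
  })
  log <- do.call(rbind, logs)
  log$subject_id <- subject_id
  log
}

#' Simulate a group of subjects
#'
#' @inheritParams simulateSubject
#' @param n_subjects Number of subjects.
#' @return Combined trial log with a `subject_id` column (`"s01"`, ...).
#' @export
simulateExperiment <- function(config, params, variant = "blind",
                               n_subjects = 28L, seed = 1L) {
  logs <- lapply(seq_len(n_subjects), function(i) {
    simulateSubject(config, params, variant,
                    seed = deriveSeed(seed, paste0("subject", i)),
                    subject_id = sprintf("s%02d", i))
  })
  do.call(rbind, logs)
}
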