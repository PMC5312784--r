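## Forward replay of the hidden-Markov belief over one block of observed
## choices and feedback. The belief is referenced to the mapping the subject
## actually applied on each trial, so the trajectory depends only on the
## data, not on alpha: the entropy-aversion rule enters purely as a threshold
## on (p, H), which is what makes the grid fit cheap and exact.
beliefReplay <- function(applied, feedback, h, rho) {
  n <- length(applied)
  p <- H <- I <- numeric(n)
  b <- 0.5
  for (t in seq_len(n)) {
    b <- transitionBelief(b, h)
    if (t > 1 && applied[t] != applied[t - 1]) b <- 1 - b
    up <- updateBelief(b, feedback[t], rho)
    b <- up$p
    p[t] <- up$p; H[t] <- up$H; I[t] <- up$I
  }
  data.frame(p = p, H = H, I = I)
}

## Decision table over a (possibly multi-block, multi-subject) trial log:
## one row per trial with a predecessor in the same block, carrying the
## belief state after the previous trial and whether the subject switched.
decisionTable <- function(log, h, rho) {
  key <- interaction(log$subject_id %||% "s", log$block_index, drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(log)), key), function(idx) {
    idx <- idx[order(log$trial_index[idx])]
    applied <- log$applied_mapping[idx]
    rep <- beliefReplay(applied, log$feedback[idx], h, rho)
    n <- length(idx)
    if (n < 2) return(NULL)
    data.frame(
      p_prev = rep$p[-n], H_prev = rep$H[-n],
      obs_switch = applied[-1] != applied[-n],
      instruction = log$instruction[idx][-1])
  })
  do.call(rbind, pieces)
}

## Mismatch count per grid value of alpha for a set of decision rows.
mismatchCurve <- function(dt, grid) {
  below <- dt$p_prev < 0.5
  m0 <- sum(dt$obs_switch & !below)          # predicted stay regardless of alpha
  Hd <- dt$H_prev[below]
  obs <- dt$obs_switch[below]
  vapply(grid, function(a) {
    pred <- Hd <= a
    m0 + sum(pred != obs)
  }, numeric(1))
}

#' Replay a fitted model over observed choices
#'
#' Runs the hidden-Markov belief forward on a subject's observed choices and
#' feedback, and derives the model's deterministic predicted choice for every
#' trial from the entropy-aversion rule applied to the belief after the
#' preceding trial. The first trial of each block, where the belief is at its
#' uninformative prior, is predicted as the observed choice. The
#' log-likelihood uses the lapse response model: each trial contributes
#' `log(1 - epsilon)` when the prediction matches the observed choice and
#' `log(epsilon)` otherwise.
#'
#' @param log Trial-log data frame (single subject).
#' @param params [agentParams()]; `alpha` unnamed for the blind variant,
#'   named per instruction for the sensitive variant; `epsilon` is the lapse
#'   rate of the likelihood.
#' @param variant `"blind"` or `"instruction_sensitive"`.
#' @return List with `predicted` (mapping per trial, in log order), `logL`,
#'   and `pct_predicted` (percent of trials where the deterministic
#'   prediction matches the observed choice).
#' @export
predictChoices <- function(log, params,
                           variant = c("blind", "instruction_sensitive")) {
  variant <- match.arg(variant)
  key <- interaction(log$subject_id %||% "s", log$block_index, drop = TRUE)
  predicted <- character(nrow(log))
  for (idx in split(seq_len(nrow(log)), key)) {
    idx <- idx[order(log$trial_index[idx])]
    applied <- log$applied_mapping[idx]
    rep <- beliefReplay(applied, log$feedback[idx], params$h, params$rho)
    alpha <- if (variant == "blind") unname(params$alpha[1]) else
      unname(params$alpha[log$instruction[idx][1]])
    if (is.na(alpha)) stop("no alpha for instruction: ",
                           log$instruction[idx][1])
    n <- length(idx)
    pred <- applied
    if (n > 1) {
      sw <- rep$p[-n] < 0.5 & rep$H[-n] <= alpha
      pred[-1] <- ifelse(sw, otherMapping(applied[-n]), applied[-n])
    }
    predicted[idx] <- pred
  }
  match <- predicted == log$applied_mapping
  eps <- params$epsilon
  if (eps == 0 && any(!match))
    stop("epsilon = 0 with mismatched predictions gives logL = -Inf")
  logL <- sum(ifelse(match, log(1 - eps), log(max(eps, .Machine$double.xmin))))
  list(predicted = predicted, logL = logL,
       pct_predicted = 100 * mean(match))
}

#' Fit the entropy-aversion parameter for one subject
#'
#' Exhaustive grid search over `alpha` in steps of 0.01 on `[0, 1]` (the
#' full range of a binary entropy in bits), maximising the lapse-model
#' log-likelihood of [predictChoices()]. The lapse rate is profiled
#' analytically at each grid point as the observed mismatch rate, clipped to
#' `[0.01, 0.49]`; ties are broken toward the smallest `alpha`. The
#' instruction-sensitive variant fits one `alpha` per instruction; because
#' blocks are independent and each block is governed by a single instruction,
#' the joint grid decomposes and the search remains exhaustive and exact.
#'
#' Free-parameter counts for the BIC are 2 for the blind variant (`alpha`
#' plus the shared lapse nuisance) and 2 + (number of instructions - 1) for
#' the sensitive variant, so the BIC difference reflects only the extra
#' `alpha` structure.
#'
#' @param log Trial log of a single subject.
#' @param variant `"blind"` or `"instruction_sensitive"`.
#' @param h,rho Fixed hazard and assumed reliability of the replayed
#'   observer.
#' @param grid Grid of candidate `alpha` values.
#' @return One-row data frame: `subject_id`, `variant`, `alpha` (blind fit;
#'   `NA` for sensitive) or `alpha_<instruction>` columns (sensitive fit),
#'   `epsilon`, `logL`, `pct_predicted`, `k`, `n`, `bic`.
#' @export
fitAlpha <- function(log, variant = c("blind", "instruction_sensitive"),
                     h = 0.03, rho = 0.75, grid = seq(0, 1, by = 0.01)) {
  variant <- match.arg(variant)
  if (nrow(log) == 0) stop("empty trial log")
  if (length(unique(log$applied_mapping)) < 2)
    warning("degenerate log: one mapping never observed")
  dt <- decisionTable(log, h, rho)
  n <- nrow(log)
  n_first <- n - nrow(dt)               # block-initial trials always match
  if (variant == "blind") {
    M <- mismatchCurve(dt, grid)
    best <- which.min(M)                 # first minimum = smallest alpha
    alphas <- c(alpha = grid[best])
    mismatches <- M[best]
    k <- 2L
  } else {
    instrs <- sort(unique(log$instruction))
    alphas <- numeric(0)
    mismatches <- 0
    for (ins in instrs) {
      Mi <- mismatchCurve(dt[dt$instruction == ins, , drop = FALSE], grid)
      best <- which.min(Mi)
      alphas[paste0("alpha_", ins)] <- grid[best]
      mismatches <- mismatches + Mi[best]
    }
    k <- 1L + length(instrs)
  }
  eps <- min(max(mismatches / n, 0.01), 0.49)
  logL <- (n - mismatches) * log(1 - eps) + mismatches * log(eps)
  out <- data.frame(subject_id = log$subject_id[1] %||% "s",
                    variant = variant, t(alphas), epsilon = eps,
                    logL = logL, pct_predicted = 100 * (n - mismatches) / n,
                    k = k, n = n, bic = bic(logL, k, n))
  rownames(out) <- NULL
  out
}

#' Fit every subject in a combined trial log
#'
#' @param log Trial log with a `subject_id` column.
#' @inheritParams fitAlpha
#' @return Data frame with one [fitAlpha()] row per subject.
#' @export
fitSubjects <- function(log, variant = c("blind", "instruction_sensitive"),
                        h = 0.03, rho = 0.75, grid = seq(0, 1, by = 0.01)) {
  variant <- match.arg(variant)
  fits <- lapply(split(log, log$subject_id), fitAlpha, variant = variant,
                 h = h, rho = rho, grid = grid)
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out[order(out$subject_id), , drop = FALSE]
}

#' Bayesian information criterion
#'
#' `BIC = k ln(n) - 2 logL`; lower is better.
#'
#' @param logL Log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return Numeric BIC value.
#' @export
bic <- function(logL, k, n) {
  stopifnot(n >= 1)
  k * log(n) - 2 * logL
}

#' Compare the instruction-blind and instruction-sensitive fits
#'
#' Fixed-effects model comparison: per-subject and summed BIC differences
#' (blind minus sensitive, so positive values favour the
#' instruction-sensitive model), with a verdict on the conventional
#' evidence bands for BIC differences (2: positive, 6: strong, 10: very
#' strong).
#'
#' @param fits_blind,fits_sensitive Data frames from [fitSubjects()] (or
#'   single-subject [fitAlpha()] rows) for the same subjects.
#' @return Object of class `model_comparison`: list with `per_subject`
#'   (data frame `subject_id`, `delta_bic`), `delta_bic_total`,
#'   `delta_bic_mean`, and `verdict`.
#' @export
compareModels <- function(fits_blind, fits_sensitive) {
  fb <- fits_blind[order(fits_blind$subject_id), ]
  fs <- fits_sensitive[order(fits_sensitive$subject_id), ]
  if (!identical(fb$subject_id, fs$subject_id))
    stop("fits do not cover the same subjects")
  delta <- fb$bic - fs$bic
  total <- sum(delta)
  band <- function(d) {
    a <- abs(d)
    if (a < 2) return("inconclusive")
    lev <- if (a < 6) "positive" else if (a < 10) "strong" else "very strong"
    sprintf("%s evidence for the %s model", lev,
            if (d > 0) "instruction-sensitive" else "instruction-blind")
  }
  structure(list(
    per_subject = data.frame(subject_id = fb$subject_id, delta_bic = delta),
    delta_bic_total = total,
    delta_bic_mean = mean(delta),
    verdict = band(total)), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("BIC model comparison (blind - sensitive)\n")
  cat(sprintf("  subjects: %d\n", nrow(x$per_subject)))
  cat(sprintf("  summed delta BIC: %.2f (mean %.2f)\n",
              x$delta_bic_total, x$delta_bic_mean))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Mean signed negative reward prediction error per instruction
#'
#' Replays the model-free Rescorla-Wagner learner (one value per mapping,
#' initialised at 0.5, only the chosen mapping updated, rewards coded
#' positive = 1 / negative = 0) over the observed trial sequence, then
#' averages the signed prediction errors over trials where the error is
#' negative, restricted to pre-reversal rule-correct trials, separately per
#' instruction condition. The learner is instruction-blind by construction,
#' so matched feedback sequences yield identical means across instructions.
#'
#' @param log Trial-log data frame.
#' @param eta Learning rate (default 0.5).
#' @param q0 Initial value per mapping.
#' @return Data frame `instruction`, `mean_negative_rpe` (`NA` when no
#'   qualifying trial exists), `n_trials`.
#' @export
meanNegativeRpe <- function(log, eta = 0.5, q0 = 0.5) {
  key <- interaction(log$subject_id %||% "s", log$block_index, drop = TRUE)
  delta <- numeric(nrow(log))
  for (idx in split(seq_len(nrow(log)), key)) {
    idx <- idx[order(log$trial_index[idx])]
    q <- c(A = q0, B = q0)
    for (i in idx) {
      m <- log$applied_mapping[i]
      st <- rlStep(q[[m]], as.integer(log$feedback[i] == "positive"), eta)
      delta[i] <- st$delta
      q[[m]] <- st$q
    }
  }
  qual <- delta < 0 & log$phase == "pre_reversal" & log$rule_correct
  instrs <- sort(unique(log$instruction))
  out <- data.frame(instruction = instrs,
                    mean_negative_rpe = NA_real_, n_trials = 0L)
  for (i in seq_along(instrs)) {
    sel <- qual & log$instruction == instrs[i]
    out$n_trials[i] <- sum(sel)
    if (any(sel)) out$mean_negative_rpe[i] <- mean(delta[sel])
  }
  out
}
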