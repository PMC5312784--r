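#' Trials to repetition of the correct rule
#'
#' Given the sequence of rule-correct flags from a reference point (block
#' start, or the first post-reversal trial), returns the 1-based index,
#' relative to that reference point, of the second trial of the first pair of
#' consecutive rule-correct trials; `NA` if no such pair occurs.
#'
#' @param rule_correct Logical vector.
#' @return Integer count (at least 2) or `NA_integer_`.
#' @export
trialsToRepetition <- function(rule_correct) {
  if (length(rule_correct) < 2) return(NA_integer_)
  hit <- which(rule_correct[-1] & rule_correct[-length(rule_correct)])
  if (length(hit) == 0) NA_integer_ else hit[1] + 1L
}

#' Phase-wise response accuracy
#'
#' Percent of trials on which the applied mapping equalled the correct
#' mapping, within a phase and (optionally) instruction condition. Phase
#' labels implement the matched-trial convention: blocks without a reversal
#' carry a nominal midpoint so "pre_reversal" always means the first half and
#' "post_reversal" the second half, with equal trial counts across matched
#' block lengths.
#'
#' @param log Trial-log data frame.
#' @param phase `"pre_reversal"` or `"post_reversal"`.
#' @param instruction Optional instruction filter.
#' @param blocks Restrict to `"reversal"` or `"non_reversal"` blocks
#'   (detected from the correct-mapping sequence), or use `"all"`. The
#'   post-reversal contrast of adaptation uses reversal blocks; the
#'   second-half contrast in the absence of reversals uses non-reversal
#'   blocks.
#' @return Percentage in `[0, 100]`, or `NA_real_` if the cell is empty.
#' @export
accuracy <- function(log, phase = c("pre_reversal", "post_reversal"),
                     instruction = NULL,
                     blocks = c("all", "reversal", "non_reversal")) {
  phase <- match.arg(phase)
  blocks <- match.arg(blocks)
  sel <- log$phase == phase
  if (!is.null(instruction)) sel <- sel & log$instruction == instruction
  if (blocks != "all") {
    rev_flag <- blockReversalFlag(log)
    sel <- sel & (rev_flag == (blocks == "reversal"))
  }
  if (!any(sel)) return(NA_real_)
  100 * mean(log$rule_correct[sel])
}

## Per-trial flag: did this trial's block contain a reversal?
blockReversalFlag <- function(log) {
  key <- interaction(log$subject_id %||% "s", log$block_index, drop = TRUE)
  flag <- logical(nrow(log))
  for (idx in split(seq_len(nrow(log)), key))
    flag[idx] <- length(unique(log$correct_mapping[idx])) > 1
  flag
}

#' Switch probability after surprising negative feedback
#'
#' A surprising negative feedback is a negative feedback delivered on a
#' rule-correct trial (i.e. invalid feedback). Among such trials that have a
#' successor within the same block, this returns the fraction whose successor
#' applied the alternative mapping.
#'
#' @param log Trial-log data frame.
#' @param phase Phase of the qualifying trial, default `"pre_reversal"`.
#' @param instruction Optional instruction filter.
#' @return Probability in `[0, 1]`, or `NA_real_` with zero qualifying
#'   trials.
#' @export
switchProbabilityAfterNegative <- function(log, phase = "pre_reversal",
                                           instruction = NULL) {
  key <- interaction(log$subject_id %||% "s", log$block_index, drop = TRUE)
  n_qual <- 0L; n_switch <- 0L
  for (idx in split(seq_len(nrow(log)), key)) {
    idx <- idx[order(log$trial_index[idx])]
    n <- length(idx)
    if (n < 2) next
    for (t in seq_len(n - 1)) {
      i <- idx[t]
      if (log$feedback[i] != "negative" || !log$rule_correct[i]) next
      if (log$phase[i] != phase) next
      if (!is.null(instruction) && log$instruction[i] != instruction) next
      n_qual <- n_qual + 1L
      if (log$applied_mapping[idx[t + 1]] != log$applied_mapping[i])
        n_switch <- n_switch + 1L
    }
  }
  if (n_qual == 0L) return(NA_real_)
  n_switch / n_qual
}

#' Paired t-test, Cohen's d, and 2x2 repeated-measures ANOVA
#'
#' Thin wrappers with the conventions used throughout the package:
#' two-tailed paired t-tests; Cohen's d for paired data as the mean
#' difference divided by the standard deviation of the differences; and a
#' two-way fully-within ANOVA via `stats::aov()` with
#' `Error(subject/(f1 * f2))` strata.
#'
#' @param x,y Paired numeric vectors.
#' @return `pairedT()`: list with `t`, `df`, `p_value`, `mean_diff`.
#'   `cohenD()`: numeric effect size. `rmAnova2x2()`: data frame with one
#'   row per effect (`f1`, `f2`, `f1:f2`) and columns `F`, `df1`, `df2`,
#'   `p_value`.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0 && mean(d) == 0)
    return(list(t = 0, df = length(x) - 1, p_value = 1, mean_diff = 0))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate))
}

#' @rdname pairedT
#' @export
cohenD <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) return(0)
  mean(d) / stats::sd(d)
}

#' @rdname pairedT
#' @param data Long-format data frame for the ANOVA.
#' @param dv,within,id Column names of the dependent variable, the two
#'   within-subject factors, and the subject identifier.
#' @export
rmAnova2x2 <- function(data, dv = "y", within = c("f1", "f2"),
                       id = "subject") {
  d <- data.frame(y = data[[dv]],
                  f1 = factor(data[[within[1]]]),
                  f2 = factor(data[[within[2]]]),
                  subject = factor(data[[id]]))
  if (any(table(d$subject, d$f1, d$f2) != 1))
    stop("rmAnova2x2 needs exactly one observation per subject x cell")
  fit <- stats::aov(y ~ f1 * f2 + Error(subject / (f1 * f2)), data = d)
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      resid_row <- which(terms == "Residuals")
      rows[[length(rows) + 1L]] <- data.frame(
        effect = sub("^f1$", within[1],
                     sub("^f2$", within[2],
                         sub("^f1:f2$", paste(within, collapse = ":"),
                             terms[i]))),
        F = tab[i, "F value"], df1 = tab[i, "Df"],
        df2 = tab[resid_row, "Df"], p_value = tab[i, "Pr(>F)"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Per-block trials-to-repetition, from block start and from the first
## post-reversal trial (reversal blocks only).
blockTtr <- function(log) {
  key <- interaction(log$subject_id %||% "s", log$block_index, drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(log)), key), function(idx) {
    idx <- idx[order(log$trial_index[idx])]
    rc <- log$rule_correct[idx]
    post <- log$phase[idx] == "post_reversal"
    reversed <- length(unique(log$correct_mapping[idx])) > 1
    data.frame(subject_id = log$subject_id[idx][1] %||% "s",
               block_index = log$block_index[idx][1],
               instruction = log$instruction[idx][1],
               has_reversal = reversed,
               ttr_initial = trialsToRepetition(rc),
               ttr_post = if (reversed) trialsToRepetition(rc[post])
                          else NA_integer_)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Behavioural summary per subject and instruction condition
#'
#' Computes the study's behavioural measures from a trial log: pre-reversal
#' accuracy over all blocks and post-reversal accuracy over reversal blocks
#' (matched-trial convention, see [accuracy()]), mean
#' trials-to-repetition from block start (`ttr_initial`) and from the
#' reversal (`ttr_post`, reversal blocks only), the switch probability after
#' surprising negative feedback in the pre-reversal phase, and the
#' pre-reversal negative-feedback rate. Blocks in which the correct rule is
#' never repeated are excluded from the trials-to-repetition means and
#' counted in `ttr_excluded`.
#'
#' @param log Trial log (any number of subjects).
#' @param reversal_blocks Restrict `ttr_post` to `"all"` reversal blocks, or
#'   only the `"first"` or `"last"` reversal block per subject x condition.
#' @return Data frame, one row per subject x instruction.
#' @export
behaviourSummary <- function(log, reversal_blocks = c("all", "first", "last")) {
  reversal_blocks <- match.arg(reversal_blocks)
  if (is.null(log$subject_id)) log$subject_id <- "s"
  ttr <- blockTtr(log)
  cells <- expand.grid(subject_id = unique(log$subject_id),
                       instruction = sort(unique(log$instruction)),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sid <- cells$subject_id[i]; ins <- cells$instruction[i]
    sub <- log[log$subject_id == sid & log$instruction == ins, ]
    tsub <- ttr[ttr$subject_id == sid & ttr$instruction == ins, ]
    rev_blocks <- tsub[tsub$has_reversal, ]
    if (nrow(rev_blocks) > 0 && reversal_blocks != "all") {
      pick <- if (reversal_blocks == "first") which.min(rev_blocks$block_index)
              else which.max(rev_blocks$block_index)
      rev_blocks <- rev_blocks[pick, , drop = FALSE]
    }
    data.frame(
      subject_id = sid, instruction = ins,
      accuracy_pre = accuracy(sub, "pre_reversal"),
      accuracy_post = accuracy(sub, "post_reversal", blocks = "reversal"),
      ttr_initial = mean(tsub$ttr_initial, na.rm = TRUE),
      ttr_post = if (nrow(rev_blocks) > 0)
        mean(rev_blocks$ttr_post, na.rm = TRUE) else NA_real_,
      ttr_excluded = sum(is.na(tsub$ttr_initial)) +
        sum(is.na(rev_blocks$ttr_post)),
      p_switch_after_negative =
        switchProbabilityAfterNegative(sub, "pre_reversal"),
      negative_feedback_rate =
        100 * mean(sub$feedback[sub$phase == "pre_reversal"] == "negative"))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
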