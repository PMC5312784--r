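#' Preprocess epoched EEG
#'
#' Applies the standard epoch-level preprocessing contract: (1) trials whose
#' within-epoch peak-to-peak voltage range exceeds `reject_uv` on any scalp
#' channel (channels of the standard montage) are discarded and the count is
#' logged; (2) data are decimated to `target_rate` (the input rate must be an
#' integer multiple); (3) a zero-phase Hamming-window FIR band-pass
#' (`highpass`..`lowpass` Hz, applied forwards and backwards via
#' `signal::filtfilt`) removes out-of-band activity. The SPN pathway uses
#' `highpass = 0.05`. On finite epochs the realised high-pass edge is
#' nominal (the filter order is bounded by the epoch length); the low-pass
#' stopband is the tested contract.
#'
#' @param epochs An [EpochSet()].
#' @param highpass,lowpass Band edges in Hz.
#' @param reject_uv Peak-to-peak artifact threshold in microvolts; `NULL`
#'   disables rejection.
#' @param target_rate Output sampling rate in Hz.
#' @param filter_order FIR order; default scales 128 taps at 250 Hz, capped
#'   by the epoch length.
#' @return A preprocessed `EpochSet`; `@processing$n_rejected` holds the
#'   number of discarded trials.
#' @export
preprocessEpochs <- function(epochs, highpass = 0.1, lowpass = 24,
                             reject_uv = 100, target_rate = 250,
                             filter_order = NULL) {
  v <- voltages(epochs)
  info <- trialInfo(epochs)
  n_rejected <- 0L
  if (!is.null(reject_uv)) {
    scalp <- which(channelNames(epochs) %in% standardMontage())
    if (length(scalp) == 0) scalp <- seq_len(dim(v)[1])
    ptp <- apply(v[scalp, , , drop = FALSE], c(1, 3), function(x)
      max(x) - min(x))
    keep <- apply(ptp <= reject_uv, 2, all)
    n_rejected <- sum(!keep)
    if (!any(keep)) stop("all trials rejected by the artifact criterion")
    v <- v[, , keep, drop = FALSE]
    info <- info[keep, , drop = FALSE]
  }
  times <- epochTimes(epochs)
  fs <- samplingRate(epochs)
  if (fs != target_rate) {
    dec <- fs / target_rate
    if (dec %% 1 != 0)
      stop("sampling rate must be an integer multiple of target_rate")
    idx <- seq(1, dim(v)[2], by = dec)
    v <- v[, idx, , drop = FALSE]
    times <- times[idx]
    fs <- target_rate
  }
  nsamp <- dim(v)[2]
  ord <- filter_order %||% min(round(128 * fs / 250), 2 * ((nsamp - 1) %/% 6))
  ord <- max(2 * (ord %/% 2), 10)        # even order, sane floor
  b <- as.numeric(signal::fir1(ord, c(highpass, lowpass) / (fs / 2),
                               type = "pass",
                               window = signal::hamming(ord + 1)))
  for (tr in seq_len(dim(v)[3]))
    for (ch in seq_len(dim(v)[1]))
      v[ch, , tr] <- signal::filtfilt(b, 1, v[ch, , tr])
  out <- EpochSet(v, samplingRate = fs, times = times,
                  channelNames = channelNames(epochs), trialInfo = info,
                  timeZero = epochs@timeZero)
  out@processing <- c(epochs@processing,
                      list(n_rejected = n_rejected,
                           band_hz = c(highpass, lowpass),
                           filter_order = ord))
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and trial, the mean voltage over the baseline
#' window (default -200..-100 ms relative to the locking event). Applying
#' the correction twice is a no-op.
#'
#' @param epochs An [EpochSet()].
#' @param window Length-2 ms interval, inclusive.
#' @return Baseline-corrected `EpochSet`.
#' @export
baselineCorrect <- function(epochs, window = c(-200, -100)) {
  times <- epochTimes(epochs)
  sel <- times >= window[1] & times <= window[2]
  if (!any(sel) || window[1] < min(times) || window[2] > max(times))
    stop("baseline window lies outside the epoch")
  v <- voltages(epochs)
  base <- apply(v[, sel, , drop = FALSE], c(1, 3), mean)
  v <- sweep(v, c(1, 3), base, "-")
  out <- epochs
  out@voltages <- v
  out@processing <- c(out@processing, list(baseline_ms = window))
  out
}

#' Condition-average cluster waveform
#'
#' Averages voltages over the channels of an electrode cluster and over the
#' selected trials, yielding one time series in microvolts.
#'
#' @param epochs An [EpochSet()].
#' @param cluster Character vector of channel names (must all be present).
#' @param select Optional logical vector (length = trials) or integer trial
#'   indices; default all trials.
#' @return Data frame with columns `time_ms` and `amplitude`.
#' @export
clusterWaveform <- function(epochs, cluster, select = NULL) {
  missing_ch <- setdiff(cluster, channelNames(epochs))
  if (length(missing_ch) > 0)
    stop("cluster channels not in montage: ",
         paste(missing_ch, collapse = ", "))
  v <- voltages(epochs)
  if (is.null(select)) select <- seq_len(dim(v)[3])
  if (is.logical(select)) select <- which(select)
  if (length(select) == 0) stop("no trials selected")
  sub <- v[match(cluster, channelNames(epochs)), , select, drop = FALSE]
  data.frame(time_ms = epochTimes(epochs),
             amplitude = apply(sub, 2, mean))
}

windowIndices <- function(times, window) {
  which(times >= window[1] & times <= window[2])
}

## Widen one peak window outward, one sample at a time, while its maximum
## sits on an edge. Only the edge carrying the maximum moves; the window
## never enters the forbidden (trough) interval and never exceeds the hard
## bounds.
widenPeakWindow <- function(times, amplitude, window, forbidden,
                            hard_bounds = c(0, 800)) {
  lo <- window[1]; hi <- window[2]
  step <- if (length(times) > 1) diff(times[1:2]) else Inf
  lo_min <- hard_bounds[1]
  hi_max <- hard_bounds[2]
  if (forbidden[2] <= lo) lo_min <- max(lo_min, forbidden[2] + step / 2)
  if (forbidden[1] >= hi) hi_max <- min(hi_max, forbidden[1] - step / 2)
  repeat {
    idx <- windowIndices(times, c(lo, hi))
    if (length(idx) == 0) stop("empty peak window")
    imax <- idx[which.max(amplitude[idx])]
    on_left <- imax == idx[1]
    on_right <- imax == idx[length(idx)]
    moved <- FALSE
    if (on_left && times[idx[1]] - step >= lo_min - 1e-9 && idx[1] > 1) {
      lo <- lo - step; moved <- TRUE
    } else if (on_right && times[idx[length(idx)]] + step <= hi_max + 1e-9 &&
               idx[length(idx)] < length(times)) {
      hi <- hi + step; moved <- TRUE
    }
    if (!moved) return(list(window = c(lo, hi),
                            peak = max(amplitude[idx])))
  }
}

#' FRN base-to-peak amplitude
#'
#' Quantifies the feedback-related negativity on a (cluster- and
#' condition-averaged) waveform as the mean of the two flanking positive
#' peaks minus the intervening trough: the trough is the minimum in
#' 240..280 ms post feedback, the peaks are the maxima of the preceding
#' (160..220 ms) and following (300..420 ms) positive-going components. If a
#' peak falls on a window edge, that edge is widened outward one sample at a
#' time until the maximum is interior, without entering the trough window and
#' within hard bounds of 0 and 800 ms. With `simple = TRUE` the measure is
#' the preceding peak minus the trough only.
#'
#' @param waveform Data frame with `time_ms` and `amplitude` (from
#'   [clusterWaveform()]).
#' @param trough_window,peak1_window,peak2_window ms intervals.
#' @param widen Widen peak windows whose maximum sits on an edge.
#' @param hard_bounds Outer limits of widening, ms.
#' @param simple Use the simple base-to-peak variant.
#' @return List of class `component_amplitude`: `value` (microvolts),
#'   `component`, and `windows` actually used after widening.
#' @export
frnAmplitude <- function(waveform, trough_window = c(240, 280),
                         peak1_window = c(160, 220),
                         peak2_window = c(300, 420),
                         widen = TRUE, hard_bounds = c(0, 800),
                         simple = FALSE) {
  times <- waveform$time_ms
  amp <- waveform$amplitude
  tidx <- windowIndices(times, trough_window)
  if (length(tidx) == 0) stop("waveform does not cover the trough window")
  trough <- min(amp[tidx])
  getPeak <- function(win) {
    if (widen) widenPeakWindow(times, amp, win, trough_window, hard_bounds)
    else list(window = win, peak = max(amp[windowIndices(times, win)]))
  }
  pk1 <- getPeak(peak1_window)
  pk2 <- getPeak(peak2_window)
  value <- if (simple) pk1$peak - trough
           else mean(c(pk1$peak, pk2$peak)) - trough
  structure(list(value = value, component = "FRN",
                 windows = list(peak1 = pk1$window, trough = trough_window,
                                peak2 = pk2$window),
                 peaks = c(pk1$peak, pk2$peak), trough = trough,
                 simple = simple),
            class = "component_amplitude")
}

#' @export
print.component_amplitude <- function(x, ...) {
  cat(sprintf("%s amplitude: %.3f uV\n", x$component, x$value))
  for (w in names(x$windows))
    cat(sprintf("  %s window: %.0f..%.0f ms\n", w,
                x$windows[[w]][1], x$windows[[w]][2]))
  invisible(x)
}

#' SPN window means by laterality
#'
#' Mean amplitude of response-locked epochs in the three pre-feedback
#' windows (-600..-400, -400..-200 and -200..0 ms relative to feedback
#' onset) over the left (FC3/C3/CP3), central (FCZ/CZ/CPZ) and right
#' (FC4/C4/CP4) columns of the SPN cluster, the cells of the
#' INSTRUCTION x TIME x LATERALITY analysis.
#'
#' @param epochs Response-locked [EpochSet()].
#' @param feedback_at_ms Feedback onset relative to the response, ms
#'   (1200 in the long-interval design).
#' @param select Optional trial selection (logical or indices).
#' @return Data frame `laterality`, `window` (1..3), `window_ms`,
#'   `mean_uv`.
#' @export
spnAmplitude <- function(epochs, feedback_at_ms = 1200, select = NULL) {
  times <- epochTimes(epochs)
  windows <- list(`1` = c(-600, -400), `2` = c(-400, -200), `3` = c(-200, 0))
  if (min(times) > feedback_at_ms - 600 || max(times) < feedback_at_ms)
    stop("response-feedback interval too short for the SPN windows")
  cl <- erpClusters()
  lat <- c(left = "spn_left", central = "spn_central", right = "spn_right")
  rows <- list()
  for (l in names(lat)) {
    wf <- clusterWaveform(epochs, cl[[lat[[l]]]], select)
    for (w in names(windows)) {
      win <- feedback_at_ms + windows[[w]]
      idx <- windowIndices(times, win)
      rows[[length(rows) + 1L]] <- data.frame(
        laterality = l, window = as.integer(w),
        window_ms = sprintf("%.0f..%.0f", windows[[w]][1], windows[[w]][2]),
        mean_uv = mean(wf$amplitude[idx]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

extremumInWindow <- function(waveform, window, fun) {
  idx <- windowIndices(waveform$time_ms, window)
  if (length(idx) == 0) stop("waveform does not cover the window")
  fun(waveform$amplitude[idx])
}

#' P3, P1 and N1 amplitudes
#'
#' Fixed-window extremum measures on a cluster waveform: the P3 is the
#' maximum voltage 300..420 ms post feedback (centro-parietal cluster), the
#' P1 the maximum 60..100 ms and the N1 the minimum 140..200 ms (parietal
#' visual cluster).
#'
#' @param waveform Data frame from [clusterWaveform()].
#' @param window ms interval.
#' @return Amplitude in microvolts.
#' @export
p3Amplitude <- function(waveform, window = c(300, 420)) {
  extremumInWindow(waveform, window, max)
}

#' @rdname p3Amplitude
#' @export
p1Amplitude <- function(waveform, window = c(60, 100)) {
  extremumInWindow(waveform, window, max)
}

#' @rdname p3Amplitude
#' @export
n1Amplitude <- function(waveform, window = c(140, 200)) {
  extremumInWindow(waveform, window, min)
}

#' Label trials by next-trial behaviour
#'
#' Adds a `next_behaviour` column to a trial log: `"repeat"` when the next
#' trial in the same block applies the same mapping, `"reverse"` when it
#' applies the alternative, `NA` for the last trial of a block (no
#' successor).
#'
#' @param log Trial-log data frame.
#' @return The log with a `next_behaviour` column.
#' @export
labelNextTrialBehaviour <- function(log) {
  key <- interaction(log$subject_id %||% "s", log$block_index, drop = TRUE)
  log$next_behaviour <- NA_character_
  for (idx in split(seq_len(nrow(log)), key)) {
    idx <- idx[order(log$trial_index[idx])]
    n <- length(idx)
    if (n < 2) next
    same <- log$applied_mapping[idx[-1]] == log$applied_mapping[idx[-n]]
    log$next_behaviour[idx[-n]] <- ifelse(same, "repeat", "reverse")
  }
  log
}

#' P3 amplitude by next-trial behaviour and instruction
#'
#' For negative-feedback trials of the pre-reversal (first) block halves,
#' labelled `"repeat"` or `"reverse"` from the next trial's applied mapping,
#' computes the centro-parietal P3 per NEXT TRIAL BEHAVIOUR x INSTRUCTION
#' cell. Trials without a successor are excluded; empty cells are flagged
#' with `NA`.
#'
#' @param epochs Feedback-locked [EpochSet()] whose `trialInfo` has columns
#'   `feedback`, `phase`, `instruction` and `next_behaviour` (see
#'   [labelNextTrialBehaviour()]).
#' @return Data frame `instruction`, `next_behaviour`, `n_trials`, `p3_uv`.
#' @export
p3ByNextTrialBehaviour <- function(epochs) {
  info <- trialInfo(epochs)
  needed <- c("feedback", "phase", "instruction", "next_behaviour")
  missing_cols <- setdiff(needed, names(info))
  if (length(missing_cols) > 0)
    stop("trialInfo is missing columns: ",
         paste(missing_cols, collapse = ", "))
  base_sel <- info$feedback == "negative" & info$phase == "pre_reversal" &
    !is.na(info$next_behaviour)
  cl <- erpClusters()$centroparietal
  cells <- expand.grid(instruction = sort(unique(info$instruction)),
                       next_behaviour = c("repeat", "reverse"),
                       stringsAsFactors = FALSE)
  cells$n_trials <- 0L
  cells$p3_uv <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- base_sel & info$instruction == cells$instruction[i] &
      info$next_behaviour == cells$next_behaviour[i]
    cells$n_trials[i] <- sum(sel)
    if (any(sel))
      cells$p3_uv[i] <- p3Amplitude(clusterWaveform(epochs, cl, sel))
  }
  cells
}
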