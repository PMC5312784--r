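#' Default component templates for the synthetic ERP generator
#'
#' Raised-cosine bump templates with compact support (value
#' `A/2 (1 + cos(pi (t - latency)/halfwidth))` for
#' `|t - latency| <= halfwidth`, zero outside), chosen so every quantification
#' window has a closed-form extremum: a parietal P1 (+3 uV at 80 ms) and N1
#' (-4 uV at 168 ms), a fronto-central positivity preceding the FRN (+5 uV at
#' 188 ms), the FRN itself (-4 uV at 260 ms), and a centro-parietal P3 (+6 uV
#' at 360 ms) that spills onto the fronto-central cluster at half weight
#' (providing the FRN's second flanking peak). Supports are disjoint at each
#' component's latency and latencies sit on the 250 Hz sample grid, so
#' measured extrema equal the template amplitudes exactly in the noise-free
#' case.
#'
#' @return Data frame with columns `name`, `latency_ms`, `halfwidth_ms`,
#'   `amplitude_uv`, `topography`.
#' @export
defaultErpComponents <- function() {
  data.frame(
    name = c("P1", "N1", "P2", "FRN", "P3"),
    latency_ms = c(80, 168, 188, 260, 360),
    halfwidth_ms = c(30, 25, 28, 35, 55),
    amplitude_uv = c(3, -4, 5, -4, 6),
    topography = c("visual", "visual", "frontocentral", "frontocentral",
                   "centroparietal_fc"))
}

## Channel weight maps over the standard montage.
defaultTopographies <- function() {
  mont <- standardMontage()
  zero <- stats::setNames(rep(0, length(mont)), mont)
  weightsOn <- function(channels, w = 1) {
    out <- zero
    out[channels] <- w
    out
  }
  cl <- erpClusters()
  cp_fc <- weightsOn(cl$centroparietal, 1)
  cp_fc[cl$frontocentral] <- pmax(cp_fc[cl$frontocentral], 0.5)
  spn <- zero
  spn[cl$spn_left] <- 0.4
  spn[cl$spn_central] <- 0.7
  spn[cl$spn_right] <- 1.0
  list(visual = weightsOn(cl$visual),
       frontocentral = weightsOn(cl$frontocentral),
       centroparietal = weightsOn(cl$centroparietal),
       centroparietal_fc = cp_fc,
       spn_right_weighted = spn)
}

#' Specification of the synthetic ERP generator
#'
#' Bundles the component templates, the condition effects (additive
#' amplitude offsets keyed by a trial-log column and level), the channel
#' topographies, the noise model and the epoch geometry.
#'
#' @param components Template table, see [defaultErpComponents()].
#' @param effects `NULL`, or a data frame with columns `component`, `label`
#'   (trial-log column), `level` and `delta_uv`: the offset is added to the
#'   component's amplitude on trials whose `label` column equals `level`.
#' @param topographies Named list of channel weight vectors (weights in
#'   `[-1, 1]` over [standardMontage()]).
#' @param noise_sd Zero-mean additive noise SD in microvolts.
#' @param noise_type `"white"` or `"pink"` (1/f-shaped spectrum).
#' @param sampling_rate Hz.
#' @param window Feedback-locked epoch window, ms.
#' @param spn List for the response-locked generator: `onset_ms` (ramp
#'   onset after the response), `feedback_at_ms`, `amplitude_uv` (level
#'   reached at feedback onset; negative for an SPN), `topography`, and
#'   `window` (response-locked epoch limits, ms).
#' @return List of class `synthetic_erp_spec`.
#' @export
syntheticErpSpec <- function(components = defaultErpComponents(),
                             effects = NULL,
                             topographies = defaultTopographies(),
                             noise_sd = 0,
                             noise_type = c("white", "pink"),
                             sampling_rate = 250,
                             window = c(-500, 1500),
                             spn = list(onset_ms = 400, feedback_at_ms = 1200,
                                        amplitude_uv = -3,
                                        topography = "spn_right_weighted",
                                        window = c(-500, 1700))) {
  noise_type <- match.arg(noise_type)
  stopifnot(all(components$halfwidth_ms > 0), noise_sd >= 0)
  if (!all(components$topography %in% names(topographies)))
    stop("component topography not defined")
  if (max(vapply(topographies, function(w) max(abs(w)), numeric(1))) > 1)
    stop("topography weights must be bounded by 1 in magnitude")
  structure(list(components = components, effects = effects,
                 topographies = topographies, noise_sd = noise_sd,
                 noise_type = noise_type, sampling_rate = sampling_rate,
                 window = window, spn = spn),
            class = "synthetic_erp_spec")
}

raisedCosine <- function(times, latency, halfwidth) {
  x <- (times - latency) / halfwidth
  ifelse(abs(x) <= 1, 0.5 * (1 + cos(pi * x)), 0)
}

## Per-trial component amplitudes: template base plus all matching condition
## offsets.
componentAmplitudes <- function(spec, trial_log) {
  n <- nrow(trial_log)
  amps <- matrix(rep(spec$components$amplitude_uv, each = n), nrow = n,
                 dimnames = list(NULL, spec$components$name))
  if (!is.null(spec$effects)) {
    for (i in seq_len(nrow(spec$effects))) {
      ef <- spec$effects[i, ]
      if (!ef$label %in% names(trial_log))
        stop("effect label '", ef$label, "' is not a trial-log column")
      if (!ef$component %in% colnames(amps))
        stop("effect component '", ef$component, "' is not a template")
      hit <- !is.na(trial_log[[ef$label]]) & trial_log[[ef$label]] == ef$level
      if (!any(hit))
        stop("effect level '", ef$level, "' matches no trial")
      amps[hit, ef$component] <- amps[hit, ef$component] + ef$delta_uv
    }
  }
  amps
}

noiseArray <- function(dims, sd, type, fs) {
  if (sd == 0) return(array(0, dims))
  if (type == "white") return(array(stats::rnorm(prod(dims), 0, sd), dims))
  nsamp <- dims[2]
  freqs <- seq(0, fs, length.out = nsamp + 1)[seq_len(nsamp)]
  freqs <- pmin(freqs, fs - freqs)             # two-sided
  scale <- ifelse(freqs > 0, 1 / sqrt(freqs), 0)
  out <- array(0, dims)
  for (tr in seq_len(dims[3]))
    for (ch in seq_len(dims[1])) {
      w <- stats::fft(stats::rnorm(nsamp))
      x <- Re(stats::fft(w * scale, inverse = TRUE)) / nsamp
      out[ch, , tr] <- sd * x / stats::sd(x)
    }
  out
}

#' Generate feedback-locked synthetic epochs
#'
#' Builds one epoch per trial-log row as the sum of the spec's component
#' templates, each scaled by its per-trial amplitude (base plus condition
#' offsets) and projected through its channel topography, plus additive
#' noise. Bit-identical under a fixed seed. The realised per-trial component
#' amplitudes are emitted in `trialInfo` as `amp_<component>` columns, the
#' ground truth for injection-recovery tests.
#'
#' @param spec A [syntheticErpSpec()].
#' @param trial_log Trial-log data frame supplying the condition labels.
#' @param seed Integer seed for the noise stream.
#' @return Feedback-locked [EpochSet()] on the 32-channel montage.
#' @export
generateEpochs <- function(spec, trial_log, seed = 1L) {
  mont <- standardMontage()
  fs <- spec$sampling_rate
  times <- seq(spec$window[1], spec$window[2], by = 1000 / fs)
  nsamp <- length(times)
  ntr <- nrow(trial_log)
  amps <- componentAmplitudes(spec, trial_log)
  basis <- lapply(seq_len(nrow(spec$components)), function(k) {
    comp <- spec$components[k, ]
    outer(spec$topographies[[comp$topography]][mont],
          raisedCosine(times, comp$latency_ms, comp$halfwidth_ms))
  })
  set.seed(deriveSeed(seed, "eeg-noise"))
  v <- noiseArray(c(length(mont), nsamp, ntr), spec$noise_sd,
                  spec$noise_type, fs)
  for (tr in seq_len(ntr)) {
    sig <- matrix(0, length(mont), nsamp)
    for (k in seq_along(basis)) sig <- sig + amps[tr, k] * basis[[k]]
    v[, , tr] <- v[, , tr] + sig
  }
  info <- cbind(trial_log,
                stats::setNames(as.data.frame(amps),
                                paste0("amp_", colnames(amps))))
  EpochSet(v, samplingRate = fs, times = times, channelNames = mont,
           trialInfo = info, timeZero = "feedback")
}

#' Generate response-locked synthetic epochs with an SPN ramp
#'
#' Emulates the long response-feedback interval design: epochs locked to the
#' response, feedback at `spec$spn$feedback_at_ms` (1200 ms), and a slow
#' negative potential that ramps linearly from `onset_ms` to its per-trial
#' amplitude at feedback onset and holds thereafter, projected through a
#' right-weighted centro-central topography so a laterality gradient is
#' present by construction. Condition offsets on the `"SPN"` component apply
#' to the ramp amplitude; per-trial ground truth is emitted as `amp_SPN`.
#'
#' @inheritParams generateEpochs
#' @return Response-locked [EpochSet()].
#' @export
generateSpnEpochs <- function(spec, trial_log, seed = 1L) {
  mont <- standardMontage()
  fs <- spec$sampling_rate
  sp <- spec$spn
  times <- seq(sp$window[1], sp$window[2], by = 1000 / fs)
  ntr <- nrow(trial_log)
  spn_spec <- spec
  spn_spec$components <- data.frame(
    name = "SPN", latency_ms = NA, halfwidth_ms = 1,
    amplitude_uv = sp$amplitude_uv, topography = sp$topography)
  amps <- componentAmplitudes(spn_spec, trial_log)
  ramp <- pmin(pmax((times - sp$onset_ms) /
                      (sp$feedback_at_ms - sp$onset_ms), 0), 1)
  basis <- outer(spec$topographies[[sp$topography]][mont], ramp)
  set.seed(deriveSeed(seed, "spn-noise"))
  v <- noiseArray(c(length(mont), length(times), ntr), spec$noise_sd,
                  spec$noise_type, fs)
  for (tr in seq_len(ntr)) v[, , tr] <- v[, , tr] + amps[tr, 1] * basis
  info <- cbind(trial_log, amp_SPN = amps[, 1])
  EpochSet(v, samplingRate = fs, times = times, channelNames = mont,
           trialInfo = info, timeZero = "response")
}
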