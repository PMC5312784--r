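# Raised-cosine bump evaluated on a time grid; the closed-form building
# block for the oracle waveforms used throughout this file.
bump <- function(times, lat, hw, amp) {
  x <- (times - lat) / hw
  amp * ifelse(abs(x) <= 1, 0.5 * (1 + cos(pi * x)), 0)
}

test_that("cluster waveforms average channels then trials", {
  v <- array(0, c(2, 4, 2), dimnames = list(c("FZ", "CZ"), NULL, NULL))
  v[1, , 1] <- c(1, 2, 3, 4); v[2, , 1] <- c(5, 6, 7, 8)
  v[1, , 2] <- c(9, 10, 11, 12); v[2, , 2] <- c(13, 14, 15, 16)
  ep <- EpochSet(v, 250, times = c(0, 4, 8, 12), channelNames = c("FZ", "CZ"))
  wf <- clusterWaveform(ep, c("FZ", "CZ"))
  expect_equal(wf$amplitude, apply(v, 2, mean))
  # single-channel cluster is that channel's trial average
  wf1 <- clusterWaveform(ep, "FZ")
  expect_equal(wf1$amplitude, (v[1, , 1] + v[1, , 2]) / 2)
  # duplicated content: cluster of two identical channels equals one
  v2 <- v; v2[2, , ] <- v2[1, , ]
  ep2 <- EpochSet(v2, 250, c(0, 4, 8, 12), c("FZ", "CZ"))
  expect_equal(clusterWaveform(ep2, c("FZ", "CZ"))$amplitude,
               clusterWaveform(ep2, "FZ")$amplitude)
  # trial selection
  expect_equal(clusterWaveform(ep, "FZ", select = 2)$amplitude, v[1, , 2])
  expect_error(clusterWaveform(ep, "PZ"), "not in montage")
  expect_error(clusterWaveform(ep, "FZ", select = logical(2)), "no trials")
})

test_that("FRN base-to-peak equals the analytic value on constructed waveforms", {
  times <- seq(0, 800, by = 4)
  flat <- data.frame(time_ms = times, amplitude = 0)
  expect_equal(frnAmplitude(flat)$value, 0)

  # three disjoint bumps with analytic extrema inside the windows
  amp <- bump(times, 188, 25, 5) + bump(times, 260, 18, -4) +
    bump(times, 348, 30, 6)
  wf <- data.frame(time_ms = times, amplitude = amp)
  res <- frnAmplitude(wf)
  expect_equal(res$value, mean(c(5, 6)) - (-4))     # 9.5
  expect_equal(res$windows$peak1, c(160, 220))      # no widening needed
  expect_equal(res$windows$peak2, c(300, 420))
  expect_equal(res$trough, -4)

  # simple variant: preceding peak minus trough
  expect_equal(frnAmplitude(wf, simple = TRUE)$value, 5 - (-4))
})

test_that("peak windows widen deterministically on ramp inputs", {
  times <- seq(0, 1000, by = 4)
  wf <- data.frame(time_ms = times, amplitude = times / 100)

  res <- frnAmplitude(wf)
  res2 <- frnAmplitude(wf)
  expect_identical(res, res2)                       # deterministic, terminates

  # brute-force oracle with the documented rule: on a strictly increasing
  # ramp the first peak window grows right until just before the trough
  # window, the second until the 800 ms hard bound
  expect_equal(res$windows$peak1[2], 236)
  expect_equal(res$windows$peak2[2], 800)
  peak1 <- max(wf$amplitude[times >= 160 & times <= 236])
  peak2 <- max(wf$amplitude[times >= 300 & times <= 800])
  trough <- min(wf$amplitude[times >= 240 & times <= 280])
  expect_equal(res$value, mean(c(peak1, peak2)) - trough)

  # decreasing ramp widens the left edges toward the bounds instead
  wfd <- data.frame(time_ms = times, amplitude = -times / 100)
  resd <- frnAmplitude(wfd)
  expect_equal(resd$windows$peak1[1], 0)
  expect_equal(resd$windows$peak2[1], 284)
})

test_that("SPN window means follow the closed form and laterality structure", {
  # flat epochs: all window means zero
  ep <- flatEpochs(2, fs = 250, window = c(-500, 1700))
  ep@timeZero <- "response"
  out <- spnAmplitude(ep)
  expect_equal(out$mean_uv, rep(0, 9))
  expect_equal(nrow(out), 9)

  # linearly decreasing potential: means strictly decrease window 1 -> 3
  times <- epochTimes(ep)
  v <- voltages(ep)
  for (tr in 1:2) v[, , tr] <- matrix(rep(-times / 1000, each = 32), 32)
  ep2 <- EpochSet(v, 250, times, channelNames(ep), timeZero = "response")
  out2 <- spnAmplitude(ep2)
  for (l in unique(out2$laterality)) {
    m <- out2$mean_uv[out2$laterality == l]
    expect_true(all(diff(m) < 0))
    # closed form: mean of -t/1000 over each window's grid
    win1 <- times >= 600 & times <= 800
    expect_equal(m[1], mean(-times[win1] / 1000))
  }

  # left/right symmetric input has a zero laterality effect
  expect_equal(out2$mean_uv[out2$laterality == "left"],
               out2$mean_uv[out2$laterality == "right"])

  short <- flatEpochs(1, window = c(-100, 300))
  expect_error(spnAmplitude(short), "too short")
})

test_that("P3, P1 and N1 take window extrema, not global ones", {
  times <- seq(0, 800, by = 4)
  flat <- data.frame(time_ms = times, amplitude = 0)
  expect_equal(p3Amplitude(flat), 0)
  expect_equal(p1Amplitude(flat), 0)
  expect_equal(n1Amplitude(flat), 0)

  wf <- data.frame(time_ms = times, amplitude = bump(times, 360, 40, 8))
  expect_equal(p3Amplitude(wf), 8)

  wf2 <- data.frame(time_ms = times,
                    amplitude = bump(times, 80, 20, 3) +
                      bump(times, 168, 25, -4))
  expect_equal(p1Amplitude(wf2), 3)
  expect_equal(n1Amplitude(wf2), -4)

  # a bump outside the window contributes only its tail at the window edge
  out_bump <- data.frame(time_ms = times, amplitude = bump(times, 500, 60, 8))
  expect_equal(p3Amplitude(out_bump),
               max(out_bump$amplitude[times >= 300 & times <= 420]))
  expect_lt(p3Amplitude(out_bump), 8)
})

test_that("component measures ignore trial order and channels outside the cluster", {
  log <- data.frame(instruction = rep(c("volatility", "stability"), each = 10))
  spec <- syntheticErpSpec(noise_sd = 2)
  ep <- generateEpochs(spec, log, seed = 9)
  perm <- sample(nTrials(ep))
  ep_perm <- subsetTrials(ep, perm)
  cl <- erpClusters()$frontocentral
  sel <- trialInfo(ep)$instruction == "volatility"
  sel_perm <- trialInfo(ep_perm)$instruction == "volatility"
  expect_equal(frnAmplitude(clusterWaveform(ep, cl, sel))$value,
               frnAmplitude(clusterWaveform(ep_perm, cl, sel_perm))$value)

  # corrupting non-cluster channels changes nothing
  v <- voltages(ep)
  v[match(c("O1", "O2", "T7"), channelNames(ep)), , ] <- 999
  ep_noisy <- EpochSet(v, 250, epochTimes(ep), channelNames(ep),
                       trialInfo(ep))
  expect_equal(frnAmplitude(clusterWaveform(ep_noisy, cl, sel))$value,
               frnAmplitude(clusterWaveform(ep, cl, sel))$value)
})

test_that("P3 splits by next-trial behaviour with boundary trials excluded", {
  # negative pre-reversal trials; next trial repeats or reverses
  log <- toyLog(c("A", "A", "B", "B", "A", "A"),
                rep("negative", 6))
  log <- labelNextTrialBehaviour(log)
  expect_equal(log$next_behaviour,
               c("repeat", "reverse", "repeat", "reverse", "repeat", NA))

  spec <- syntheticErpSpec(
    effects = data.frame(component = "P3", label = "next_behaviour",
                         level = "reverse", delta_uv = 3),
    noise_sd = 0)
  ep <- generateEpochs(spec, log[!is.na(log$next_behaviour), ], seed = 1)
  out <- p3ByNextTrialBehaviour(ep)
  rev_amp <- out$p3_uv[out$next_behaviour == "reverse"]
  rep_amp <- out$p3_uv[out$next_behaviour == "repeat"]
  expect_equal(rev_amp - rep_amp, 3)
  expect_equal(sum(out$n_trials), 5)       # boundary trial dropped upstream

  # with no injected effect the split is exactly null
  ep0 <- generateEpochs(syntheticErpSpec(noise_sd = 0),
                        log[!is.na(log$next_behaviour), ], seed = 1)
  out0 <- p3ByNextTrialBehaviour(ep0)
  expect_equal(diff(range(out0$p3_uv)), 0)

  # last trial of each block never enters a cell
  ep_all <- generateEpochs(syntheticErpSpec(noise_sd = 0), log, seed = 1)
  out_all <- p3ByNextTrialBehaviour(ep_all)
  expect_equal(sum(out_all$n_trials), 5)
})
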