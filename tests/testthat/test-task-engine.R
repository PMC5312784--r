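test_that("exp1a schedules are exactly counterbalanced for every seed", {
  cfg <- experimentConfig("exp1a")
  for (seed in 1:4) {
    s <- buildSchedule(cfg, seed)
    expect_equal(nrow(s), 36)
    tab <- table(s$instruction, s$has_reversal)
    expect_equal(unname(tab["volatility", "TRUE"]), 12)
    expect_equal(unname(tab["volatility", "FALSE"]), 6)
    expect_equal(unname(tab["stability", "TRUE"]), 6)
    expect_equal(unname(tab["stability", "FALSE"]), 12)
    # lengths crossed evenly with instruction and reversal status
    expect_true(all(table(s$instruction, s$length) == 6))
    cell <- table(s$instruction, s$length, s$has_reversal)
    expect_true(all(cell["volatility", , "TRUE"] == 4))
    expect_true(all(cell["stability", , "TRUE"] == 2))
    expect_true(all(s$reliability == 0.75))
  }
})

test_that("exp2 schedules carry four block types with equal reversal counts", {
  cfg <- experimentConfig("exp2")
  s <- buildSchedule(cfg, seed = 7)
  expect_equal(nrow(s), 32)
  expect_equal(sum(s$has_reversal), 24)   # 3/4 of the blocks
  type <- interaction(s$instruction, s$reliability, drop = TRUE)
  expect_equal(sort(as.vector(table(type))), c(8L, 8L, 8L, 8L))
  for (ty in levels(type)) {
    sub <- s[type == ty, ]
    expect_equal(sum(sub$has_reversal), 6)
    expect_equal(sort(sub$reversal_trial[sub$has_reversal]),
                 rep(c(9L, 17L, 25L), each = 2))
  }
  expect_equal(sum(s$reliability == 0.875), 8)
  expect_equal(sum(s$reliability == 0.625), 8)
  expect_equal(sum(s$reliability == 0.75), 16)
})

test_that("non-divisible counterbalancing raises a configuration error", {
  cfg <- experimentConfig("exp1a")
  cfg$n_blocks <- 20L
  expect_error(buildSchedule(cfg, 1), "does not divide")
})

test_that("exp1b schedules exist and respect totals despite the odd block count", {
  cfg <- experimentConfig("exp1b")
  s <- buildSchedule(cfg, seed = 3)
  expect_equal(nrow(s), 27)
  expect_true(all(s$length %in% c(25, 33, 41)))
  # reversal totals follow the 2/3 and 1/3 targets to rounding
  n_v <- sum(s$instruction == "volatility")
  expect_lte(abs(sum(s$has_reversal[s$instruction == "volatility"]) -
                   2 / 3 * n_v), 1)
})

test_that("reversal trials match the printed designs", {
  expect_equal(reversalTrialFor(25, "exp1a"), 13L)
  expect_equal(reversalTrialFor(33, "exp1a"), 17L)
  expect_equal(reversalTrialFor(41, "exp1b"), 21L)
  expect_error(reversalTrialFor(29, "exp1a"), "unsupported")
  set.seed(1)
  expect_true(all(replicate(20, reversalTrialFor(33, "exp2")) %in%
                    c(9, 17, 25)))
  expect_error(reversalTrialFor(25, "exp2"), "unsupported")
})

test_that("zero reversal probability yields a reversal-free schedule", {
  cfg <- experimentConfig("exp1a")
  cfg$instruction_reversal_prob[] <- 0
  s <- buildSchedule(cfg, 2)
  expect_false(any(s$has_reversal))
  expect_true(all(is.na(s$reversal_trial)))
})

test_that("feedback validity converges to rho", {
  set.seed(101)
  n <- 1e5
  for (rho in c(0.875, 0.75, 0.625)) {
    fb <- drawFeedback(rep(FALSE, n), rho)
    se <- sqrt(rho * (1 - rho) / n)
    expect_lt(abs(mean(fb$valid) - rho), 3 * se)
    # invalid feedback on incorrect responses is positive
    expect_true(all(fb$feedback[!fb$valid] == "positive"))
  }
  fb <- drawFeedback(rep(TRUE, 100), 1.0)
  expect_true(all(fb$feedback == "positive"))
})

test_that("an always-correct agent sees the design negative-feedback rate", {
  blocks <- lapply(1:300, function(i) toyBlock(index = i))
  logs <- lapply(blocks, function(b) runBlock(b, oracleAgent(), seed = b$index))
  log <- do.call(rbind, logs)
  n <- nrow(log)
  expect_gte(n, 9000)
  rate <- mean(log$feedback == "negative")
  expect_lt(abs(rate - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_true(all(log$rule_correct))
  # valid feedback on correct trials is positive, invalid is negative
  expect_true(all((log$feedback == "positive") == log$feedback_valid))
})

test_that("the correct mapping flips once at the reversal and phases split there", {
  log <- runBlock(toyBlock(length = 33L, reversal_trial = 17L),
                  oracleAgent(), seed = 5)
  expect_equal(unique(log$correct_mapping[1:16]), "A")
  expect_equal(unique(log$correct_mapping[17:33]), "B")
  expect_true(all(log$phase[1:16] == "pre_reversal"))
  expect_true(all(log$phase[17:33] == "post_reversal"))
  # both stimuli appear on floor/ceiling(length/2) trials
  expect_equal(sort(as.vector(table(log$stimulus_id))), c(16L, 17L))

  log2 <- runBlock(toyBlock(has_reversal = FALSE), oracleAgent(), seed = 5)
  expect_equal(unique(log2$correct_mapping), "A")
  expect_equal(sum(log2$phase == "pre_reversal"), 16)
})

test_that("pre-reversal trial counts match across instructions for matched lengths", {
  cfg <- experimentConfig("exp1a")
  s <- buildSchedule(cfg, 9)
  pre <- (s$length + 1) %/% 2 - 1
  for (len in cfg$block_lengths)
    expect_equal(unique(pre[s$length == len]), (len + 1) %/% 2 - 1)
  expect_equal(sum(pre[s$instruction == "volatility"]),
               sum(pre[s$instruction == "stability"]))
})

test_that("trial logs round-trip through the tab-delimited format", {
  log <- runBlock(toyBlock(), oracleAgent(), seed = 11)
  log$subject_id <- "s01"
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrialLog(log, path)
  back <- readTrialLog(path)
  expect_equal(back, log, ignore_attr = TRUE)
})

test_that("malformed or incomplete trial logs are rejected with a location", {
  log <- runBlock(toyBlock(), oracleAgent(), seed = 1)
  expect_error(writeTrialLog(log[, -3], tempfile()), "missing columns")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrialLog(log, path)
  lines <- readLines(path)
  lines[4] <- paste0(lines[4], "\textra_field")
  writeLines(lines, path)
  expect_error(readTrialLog(path), "line 4")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  log2 <- log
  names(log2)[names(log2) == "feedback"] <- "fb"
  utils::write.table(log2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readTrialLog(path2), "missing columns")
})

test_that("a hand-written three-row log parses to three trial records", {
  path <- system.file("extdata", "toy_trial_log.tsv", package = "RevLearnEEG")
  log <- readTrialLog(path)
  expect_equal(nrow(log), 3)
  expect_equal(log$applied_mapping, c("A", "B", "A"))
  expect_equal(log$rule_correct, c(TRUE, FALSE, TRUE))
  expect_equal(log$feedback_valid,
               (log$feedback == "positive") == log$rule_correct)
})

test_that("shipped configuration files reproduce the in-code defaults", {
  for (id in c("exp1a", "exp1b", "exp2")) {
    path <- system.file("extdata", paste0(id, ".yml"),
                        package = "RevLearnEEG")
    cfg <- readExperimentConfig(path)
    ref <- experimentConfig(id)
    expect_equal(cfg$n_blocks, ref$n_blocks)
    expect_equal(cfg$block_lengths, ref$block_lengths)
    expect_equal(cfg$instruction_reversal_prob,
                 ref$instruction_reversal_prob, tolerance = 1e-12)
    expect_equal(cfg$reliability_levels, ref$reliability_levels)
    expect_equal(cfg$instructions, ref$instructions)
  }
  # a schedule built from the file-based config is valid
  s <- buildSchedule(readExperimentConfig(
    system.file("extdata", "exp1a.yml", package = "RevLearnEEG")), seed = 1)
  expect_equal(sum(s$has_reversal), 18)

  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("experiment_id: exp9", bad)
  expect_error(readExperimentConfig(bad), "missing fields")
})
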