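test_that("markov_params validates its probability structure", {
  expect_error(markov_params(start_probs = c(0.5, 0.4, 0.2)),
               class = "rdyn_config_error")
  expect_error(markov_params(stop_hazard = c(0.1, 1.0, 0.1)),
               class = "rdyn_config_error")
  bad <- matrix(c(0.5, 0.5, 0.5, 0.3, 0.4, 0.3, 0.3, 0.3, 0.4), 3, 3,
                byrow = TRUE)
  expect_error(markov_params(stay_switch = bad),
               class = "rdyn_config_error")
})

test_that("a pure-positive start distribution always starts positive", {
  stim <- fix_list_sets()$set1
  stim <- stim[stim$list_id == stim$list_id[1], ]
  p <- markov_params(start_probs = c(positive = 1, negative = 0,
                                     neutral = 0))
  set.seed(2)
  cats <- stim$category[match(
    vapply(1:50, function(i) simulate_recall(p, stim)[1], character(1)),
    stim$word)]
  expect_true(all(cats == "positive"))
})

test_that("near-one hazards end almost every sequence after one recall", {
  stim <- micro_lists()
  p <- markov_params(stop_hazard = c(0.99, 0.99, 0.99))
  set.seed(3)
  lens <- vapply(1:3000, function(i) length(simulate_recall(p, stim)),
                 numeric(1))
  expect_gte(mean(lens == 1), 0.98)
})

test_that("simulated sequences never repeat a word and respect item counts", {
  stim <- fix_list_sets()$set1
  stim <- stim[stim$list_id == stim$list_id[1], ]
  p <- markov_params(stop_hazard = c(0.05, 0.05, 0.05))
  set.seed(4)
  for (i in 1:500) {
    words <- simulate_recall(p, stim)
    expect_false(anyDuplicated(words) > 0)
    cats <- stim$category[match(words, stim$word)]
    expect_true(all(table(cats) <= 6))
    expect_false(any(stim$is_buffer[match(words, stim$word)]))
  }
})

test_that("block randomization fills blocks at the 3:2 ratio", {
  set.seed(5)
  g5 <- block_randomize(5)
  expect_equal(sum(g5 == "MBCT"), 3)
  expect_equal(sum(g5 == "control"), 2)
  g10 <- block_randomize(10)
  expect_equal(sum(g10 == "MBCT"), 6)
  ## 52 = 10 complete blocks + partial block of 2 drawn from (3 MBCT, 2 ctrl)
  counts <- vapply(1:2000, function(i) sum(block_randomize(52) == "MBCT"),
                   numeric(1))
  expect_true(all(counts %in% c(30, 31, 32)))
  ## hypergeometric probabilities of the partial block: 1/10, 6/10, 3/10
  emp <- tabulate(factor(counts, levels = 30:32)) / 2000
  expected <- c(dhyper(0, 3, 2, 2), dhyper(1, 3, 2, 2), dhyper(2, 3, 2, 2))
  for (j in 1:3) {
    se <- sqrt(expected[j] * (1 - expected[j]) / 2000)
    expect_lt(abs(emp[j] - expected[j]), 4 * se)
  }
  expect_error(block_randomize(10, block_size = 5, ratio = c(3, 3)),
               class = "rdyn_config_error")
})

test_that("the default simulated trial reproduces the trial design counts", {
  study <- simulate_trial(trial_design(seed = 60), lists = fix_list_sets())
  pp <- participants(study)
  expect_identical(nrow(pp), 52L)
  expect_identical(sum(pp$group == "MBCT"), 29L)
  expect_identical(sum(pp$group == "control"), 23L)
  seqs <- unique(study$events[c("participant_id", "timepoint", "list_id")])
  expect_identical(nrow(seqs), 52L * 2L * 3L)
  expect_error(trial_design(n_mbct = 0), class = "rdyn_config_error")
})

test_that("simulated trials are byte-identical under the same seed", {
  a <- simulate_trial(trial_design(3, 2, 2, seed = 61),
                      lists = fix_list_sets())
  b <- simulate_trial(trial_design(3, 2, 2, seed = 61),
                      lists = fix_list_sets())
  expect_identical(a$events, b$events)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  lp <- withr::local_tempfile(fileext = ".csv")
  write_study(a, fa, lp); write_study(b, fb, lp)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  c <- simulate_trial(trial_design(3, 2, 2, seed = 62),
                      lists = fix_list_sets())
  expect_false(identical(a$events, c$events))
})

test_that("forced single-category dynamics behave deterministically", {
  ## all starts positive, stay diagonal 1, no stopping: the model recalls
  ## all positives then halts (no mass on other categories)
  p <- markov_params(start_probs = c(1, 0, 0),
                     stay_switch = diag(3),
                     stop_hazard = c(0, 0, 0), max_recalls = 50)
  o <- expected_metrics_oracle(p, n_per_category = 6, n_mc = 50, seed = 6)
  expect_equal(o$value[o$metric == "pstart" & o$category == "positive"], 1)
  expect_equal(o$value[o$metric == "pstay" & o$category == "positive"], 1)
  expect_equal(o$value[o$metric == "pstop" & o$category == "positive"],
               1 / 6)
})

test_that("the oracle approaches the raw parameters without depletion", {
  p <- markov_params(
    start_probs = c(0.2, 0.5, 0.3),
    stay_switch = matrix(c(0.7, 0.15, 0.15, 0.2, 0.6, 0.2,
                           0.25, 0.25, 0.5), 3, 3, byrow = TRUE),
    stop_hazard = c(0.1, 0.3, 0.2), max_recalls = 200)
  o <- expected_metrics_oracle(p, n_per_category = 500, n_mc = 4000,
                               seed = 7)
  expect_lt(max(abs(o$value[o$metric == "pstart"] -
                      unname(p$start_probs))), 0.035)
  expect_lt(max(abs(o$value[o$metric == "pstay"] -
                      unname(diag(p$stay_switch)))), 0.035)
  expect_lt(max(abs(o$value[o$metric == "pstop"] -
                      unname(p$stop_hazard))), 0.035)
})

test_that("planted effect parameters shift the intended cells only", {
  cp <- effect_cell_params(0.15)
  base <- markov_params()
  expect_identical(cp$MBCT.T1, base)
  expect_identical(cp$control.T1, base)
  sw <- cp$MBCT.T2$stay_switch
  expect_equal(sw["negative", "negative"],
               base$stay_switch["negative", "negative"] - 0.15)
  expect_equal(sw["positive", "positive"],
               base$stay_switch["positive", "positive"] + 0.15)
  expect_equal(unname(rowSums(sw)), rep(1, 3), tolerance = 1e-12)
  ## the planted hazard drop is floored at 0.01 (hazards cannot go negative)
  expect_equal(cp$MBCT.T2$stop_hazard[["negative"]],
               max(base$stop_hazard[["negative"]] - 0.15, 0.01))
  swc <- cp$control.T2$stay_switch
  expect_equal(swc["negative", "negative"],
               base$stay_switch["negative", "negative"] + 0.15)
  expect_equal(swc["positive", "positive"],
               base$stay_switch["positive", "positive"] - 0.15)
})
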