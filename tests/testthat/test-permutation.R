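test_that("a scheme with neither flag set is rejected", {
  expect_error(permutation_scheme(), class = "rdyn_config_error")
})

test_that("group swaps conserve the label multiset and recall content", {
  study <- small_trial(3, 2, seed = 4)
  sch <- permutation_scheme(swap_group = TRUE)
  set.seed(10)
  for (i in 1:200) {
    perm <- permute_labels(study, sch)
    expect_equal(sort(participants(perm)$group),
                 sort(participants(study)$group))
    expect_identical(sort(perm$events$word), sort(study$events$word))
  }
})

test_that("time swap of one participant yields each of two datasets about half the time", {
  study <- micro_study(list(
    list(pid = "P1", group = "MBCT", tp = "T1",
         cats = c("negative", "positive")),
    list(pid = "P1", group = "MBCT", tp = "T2",
         cats = c("positive", "neutral"))))
  sch <- permutation_scheme(swap_time = TRUE)
  set.seed(11)
  flipped <- vapply(1:1000, function(i) {
    perm <- permute_labels(study, sch)
    perm$events$timepoint[perm$events$word == "neg1"] == "T2"
  }, logical(1))
  ## binomial(1000, 1/2): 3 SD tolerance
  expect_gt(mean(flipped), 0.5 - 3 * sqrt(0.25 / 1000))
  expect_lt(mean(flipped), 0.5 + 3 * sqrt(0.25 / 1000))
})

test_that("change statistic equals the difference of pooled estimates", {
  study <- small_trial(3, 3, seed = 8)
  for (g in c("MBCT", "control")) {
    expect_equal(
      change_stat(study, "pstay", "negative", g),
      pooled_pstay(study, g, "T2", "negative")$value -
        pooled_pstay(study, g, "T1", "negative")$value)
  }
  ## identical recall data at both timepoints gives zero change
  same <- micro_study(list(
    list(pid = "P1", group = "MBCT", tp = "T1",
         cats = c("negative", "negative", "positive")),
    list(pid = "P1", group = "MBCT", tp = "T2",
         cats = c("negative", "negative", "positive"))))
  expect_equal(change_stat(same, "pstay", "negative", "MBCT"), 0)
})

test_that("interaction statistic is the difference of differences and anti-symmetric", {
  study <- small_trial(3, 3, seed = 9)
  expect_equal(interaction_stat(study, "pstart", "negative"),
               change_stat(study, "pstart", "negative", "MBCT") -
                 change_stat(study, "pstart", "negative", "control"))
  ## swapping the two arm labels negates the statistic
  swapped <- study
  swapped$events$group <- ifelse(swapped$events$group == "MBCT",
                                 "control", "MBCT")
  swapped <- recall_study(swapped$events, swapped$lists,
                          lists_per_assessment = 3)
  expect_equal(interaction_stat(swapped, "pstart", "negative"),
               -interaction_stat(study, "pstart", "negative"))
})

test_that("identical data everywhere gives p = 1", {
  seqs <- list()
  for (p in 1:4) for (tp in c("T1", "T2")) {
    seqs[[length(seqs) + 1]] <- list(
      pid = sprintf("P%d", p), group = if (p <= 2) "MBCT" else "control",
      tp = tp, cats = c("negative", "negative", "positive"))
  }
  study <- micro_study(seqs)
  r <- permutation_test(study, "pstay", "negative", "interaction",
                        n_perm = 200, seed = 5)
  expect_equal(r$observed_stat, 0)
  expect_equal(r$p_value, 1)
  ex <- exact_test(study, "pstay", "negative", "time_within_group",
                   group = "MBCT")
  expect_equal(ex$p_value, 1)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on a 6-participant fixture", {
  study <- small_trial(3, 3, seed = 6, lists_per_assessment = 2)
  ex <- exact_test(study, "pstay", "negative", "time_within_group",
                   group = "MBCT")
  expect_identical(ex$n_perm, 8L)
  mc <- permutation_test(study, "pstay", "negative", "time_within_group",
                         group = "MBCT", n_perm = 5000, seed = 12)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 5000)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 1 / 5001)
})

test_that("vectorized null statistics equal a full dataset relabel-and-recompute", {
  study <- small_trial(3, 3, seed = 14, lists_per_assessment = 2)
  counts <- recalldyn:::.participant_counts(study, "pstay", "negative")
  pp <- participants(study)
  set.seed(99)
  for (i in 1:5) {
    flip <- runif(nrow(pp)) < 0.5
    ## flipped study built by hand
    ev <- study$events
    fr <- flip[match(ev$participant_id, pp$participant_id)]
    ev$timepoint <- ifelse(fr, ifelse(ev$timepoint == "T1", "T2", "T1"),
                           ev$timepoint)
    flipped <- score_study(recall_study(ev, study$lists,
                                        lists_per_assessment = 2))
    direct <- change_stat(flipped, "pstay", "negative", "MBCT")
    ## same flip through the count matrices
    N <- counts$N; D <- counts$D
    rows <- pp$group == "MBCT"
    n2 <- ifelse(flip, N[, 1], N[, 2]); n1 <- ifelse(flip, N[, 2], N[, 1])
    d2 <- ifelse(flip, D[, 1], D[, 2]); d1 <- ifelse(flip, D[, 2], D[, 1])
    expect_equal(sum(n2[rows]) / sum(d2[rows]) -
                   sum(n1[rows]) / sum(d1[rows]), direct)
  }
})

test_that("permutation tests are deterministic given a seed", {
  study <- small_trial(4, 3, seed = 15)
  a <- permutation_test(study, "pstop", "negative", "interaction",
                        n_perm = 500, seed = 77)
  b <- permutation_test(study, "pstop", "negative", "interaction",
                        n_perm = 500, seed = 77)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$null_mean, b$null_mean)
  expect_identical(a$n_perm, 500L)
})

test_that("exact test enumerates two assignments for one participant", {
  study <- micro_study(list(
    list(pid = "P1", group = "MBCT", tp = "T1",
         cats = c("negative", "negative", "positive")),
    list(pid = "P1", group = "MBCT", tp = "T2",
         cats = c("negative", "positive", "positive"))))
  ex <- exact_test(study, "pstart", "negative", "time_within_group",
                   group = "MBCT")
  expect_identical(ex$n_perm, 2L)
  expect_true(ex$exhaustive)
})

test_that("oversized enumerations raise a capacity error", {
  study <- small_trial(8, 7, seed = 2, lists_per_assessment = 2)
  expect_error(exact_test(study, "pstay", "negative", "interaction"),
               class = "rdyn_capacity_error")
})

test_that("degenerate data fail loudly instead of imputing permuted statistics", {
  ## one MBCT participant has negative transitions only at T1, the other
  ## only at T2: half of all time-flip assignments empty one pooled cell
  study <- micro_study(list(
    list(pid = "P1", group = "MBCT", tp = "T1",
         cats = c("negative", "negative", "positive")),
    list(pid = "P1", group = "MBCT", tp = "T2", cats = c("positive")),
    list(pid = "P1b", group = "MBCT", tp = "T1", cats = c("positive")),
    list(pid = "P1b", group = "MBCT", tp = "T2",
         cats = c("negative", "negative", "positive")),
    list(pid = "P2", group = "control", tp = "T1",
         cats = c("negative", "negative")),
    list(pid = "P2", group = "control", tp = "T2",
         cats = c("negative", "negative"))))
  expect_error(
    permutation_test(study, "pstay", "negative", "time_within_group",
                     group = "MBCT", n_perm = 400, seed = 3),
    class = "rdyn_degenerate_error")
})

test_that("p-values are invariant to a consistent category relabelling", {
  study <- small_trial(3, 3, seed = 18, lists_per_assessment = 2)
  relab <- study
  map <- c(positive = "negative", negative = "positive",
           neutral = "neutral")
  relab$events$category <- unname(map[relab$events$category])
  relab$lists$category <- unname(map[relab$lists$category])
  relab <- recall_study(relab$events, relab$lists, lists_per_assessment = 2)
  a <- permutation_test(study, "pstay", "positive", "interaction",
                        n_perm = 300, seed = 21)
  b <- permutation_test(relab, "pstay", "negative", "interaction",
                        n_perm = 300, seed = 21)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$observed_stat, b$observed_stat)
})
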