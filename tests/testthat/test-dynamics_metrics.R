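test_that("Pstay and Pstop match the worked micro-example", {
  ## one list with retained categories [neg, neg, pos, neg]
  study <- micro_study(list(list(pid = "P1", group = "MBCT", tp = "T1",
                                 cats = c("negative", "negative",
                                          "positive", "negative"))))
  stay <- pooled_pstay(study, "MBCT", "T1",
                       categories = c("negative", "positive"))
  expect_equal(stay$numerator, c(1L, 0L))
  expect_equal(stay$denominator, c(2L, 1L))
  expect_equal(stay$value, c(1 / 2, 0))
  stop <- pooled_pstop(study, "MBCT", "T1",
                       categories = c("negative", "positive"))
  expect_equal(stop$numerator, c(1L, 0L))
  expect_equal(stop$denominator, c(3L, 1L))
  expect_equal(stop$value, c(1 / 3, 0))
  ## no neutral transitions: that category's estimate is undefined
  expect_error(pooled_pstay(study, "MBCT", "T1"),
               class = "rdyn_undefined_error")
})

test_that("Pstart counts first retained categories over lists", {
  firsts <- c("negative", "positive", "negative", "neutral", "positive",
              "negative")
  seqs <- lapply(seq_along(firsts), function(i) {
    list(pid = sprintf("P%d", i), group = "control", tp = "T2",
         cats = c(firsts[i], "neutral")[1:(1 + (firsts[i] != "neutral"))])
  })
  study <- micro_study(seqs)
  ps <- pooled_pstart(study, "control", "T2")
  expect_equal(ps$value[ps$category == "positive"], 2 / 6)
  expect_equal(ps$value[ps$category == "negative"], 3 / 6)
  expect_equal(ps$value[ps$category == "neutral"], 1 / 6)
  expect_equal(sum(ps$value), 1, tolerance = 1e-12)
})

test_that("terminal category distribution counts list endings and sums to 1", {
  endings <- c("negative", "negative", "positive", "neutral")
  seqs <- lapply(seq_along(endings), function(i) {
    list(pid = sprintf("P%d", i), group = "MBCT", tp = "T1",
         cats = c(setdiff(c("positive", "negative", "neutral"),
                          endings[i])[1], endings[i]))
  })
  study <- micro_study(seqs)
  td <- terminal_category_distribution(study, "MBCT", "T1")
  expect_equal(td$value[td$category == "positive"], 1 / 4)
  expect_equal(td$value[td$category == "negative"], 2 / 4)
  expect_equal(td$value[td$category == "neutral"], 1 / 4)
  expect_equal(sum(td$value), 1, tolerance = 1e-12)
})

test_that("recall percentage counts distinct targets over presented targets", {
  ## micro list has 3 targets per category; 2 of 3 negative recalled
  study <- micro_study(list(list(pid = "P1", group = "MBCT", tp = "T1",
                                 cats = c("negative", "negative"))))
  pct <- recall_percentage(study, "MBCT", "T1")
  expect_equal(pct$value[pct$category == "negative"], 100 * 2 / 3)
  expect_equal(pct$value[pct$category == "positive"], 0)
  ## order invariance: shuffling event order leaves the percentage unchanged
  study2 <- micro_study(list(list(pid = "P1", group = "MBCT", tp = "T1",
                                  cats = c("negative", "positive",
                                           "negative", "neutral"))))
  ev <- study2$events
  set.seed(1)
  for (i in 1:20) {
    perm <- sample(nrow(ev))
    shuffled <- ev[perm, ]
    shuffled$output_position <- seq_len(nrow(ev))
    s3 <- score_study(recall_study(shuffled, study2$lists,
                                   lists_per_assessment = 1))
    expect_equal(recall_percentage(s3, "MBCT", "T1")$value,
                 recall_percentage(study2, "MBCT", "T1")$value)
  }
})

test_that("repetitions and intrusions do not inflate recall percentages", {
  study <- micro_study(list(list(
    pid = "P1", group = "control", tp = "T1",
    cats = c("positive", "positive", "positive"),
    extra_words = c("pos1", "zzzz", "pos2"))))
  pct <- recall_percentage(study, "control", "T1")
  expect_equal(pct$value[pct$category == "positive"], 100)
})

test_that("pooling aggregates counts before division, not per-participant means", {
  ## P1: 1 stay / 1 transition; P2: 1 stay / 4 transitions
  study <- micro_study(list(
    list(pid = "P1", group = "MBCT", tp = "T1",
         cats = c("negative", "negative")),
    list(pid = "P2", group = "MBCT", tp = "T1",
         cats = c("negative", "negative", "positive", "negative",
                  "positive"))))
  stay <- pooled_pstay(study, "MBCT", "T1", categories = "negative")
  ## pooled: (1 + 1) / (1 + 3) = 0.5; participant-mean would be 0.667
  expect_equal(stay$value, 0.5)
  expect_false(isTRUE(all.equal(stay$value, mean(c(1 / 1, 1 / 3)))))
})

test_that("stay plus switch counts conserve transitions on simulated data", {
  study <- small_trial(4, 3, seed = 21)
  for (g in c("MBCT", "control")) for (tp in c("T1", "T2")) {
    stay <- pooled_pstay(study, g, tp)
    ## independent transition count from the retained sequences
    ev <- study$events[study$events$classification == "target", ]
    ev <- ev[ev$group == g & ev$timepoint == tp, ]
    ev <- ev[order(ev$participant_id, ev$list_id, ev$output_position), ]
    key <- paste(ev$participant_id, ev$list_id)
    trans_from <- ev$category[-nrow(ev)][key[-nrow(ev)] == key[-1]]
    expect_equal(sum(stay$denominator), length(trans_from))
    for (cat in c("positive", "negative", "neutral")) {
      expect_equal(stay$denominator[stay$category == cat],
                   sum(trans_from == cat))
    }
  }
})

test_that("Pstart and terminal distributions sum to one on simulated data", {
  study <- small_trial(5, 4, seed = 33)
  for (g in c("MBCT", "control")) for (tp in c("T1", "T2")) {
    expect_equal(sum(pooled_pstart(study, g, tp)$value), 1,
                 tolerance = 1e-12)
    expect_equal(sum(terminal_category_distribution(study, g, tp)$value), 1,
                 tolerance = 1e-12)
  }
})

test_that("empty cells raise undefined-metric errors naming the cell", {
  study <- micro_study(list(list(pid = "P1", group = "MBCT", tp = "T1",
                                 cats = c("negative", "positive"))))
  err <- expect_error(pooled_pstart(study, "control", "T1"),
                      class = "rdyn_undefined_error")
  expect_match(conditionMessage(err), "control")
  expect_error(recall_percentage(study, "control", "T1"),
               class = "rdyn_undefined_error")
})

test_that("numerator and denominator are recoverable integers consistent with value", {
  study <- small_trial(3, 3, seed = 77)
  tab <- dynamics_table(study)
  ok <- !is.na(tab$value)
  expect_true(all(tab$numerator[ok] <= tab$denominator[ok]))
  scale <- ifelse(tab$metric[ok] == "recall_pct", 100, 1)
  expect_equal(tab$value[ok],
               scale * tab$numerator[ok] / tab$denominator[ok])
  expect_true(all(tab$value[ok] >= 0 & tab$value[ok] <= 100))
})
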