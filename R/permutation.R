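#' Define a label-permutation scheme
#'
#' @param swap_group shuffle group labels across participants (arm sizes
#'   preserved).
#' @param swap_time flip each participant's T1/T2 labels independently with
#'   probability 1/2, all of a participant's lists moving together.
#' @return object of class `permutation_scheme`. At least one flag must be
#'   set.
#' @export
permutation_scheme <- function(swap_group = FALSE, swap_time = FALSE) {
  if (!isTRUE(swap_group) && !isTRUE(swap_time)) {
    abort_config("permutation scheme must set swap_group and/or swap_time")
  }
  structure(list(swap_group = isTRUE(swap_group),
                 swap_time = isTRUE(swap_time)),
            class = "permutation_scheme")
}

#' Randomly permute design labels of a study
#'
#' Applies one random draw of the scheme to the dataset: group labels are a
#' uniform random permutation of the observed labels across participants,
#' and/or each participant's T1/T2 labels are independently exchanged with
#' probability 1/2. All recall content is unchanged. Uses the current RNG
#' state.
#'
#' @param study a `recall_study`.
#' @param scheme a [permutation_scheme()].
#' @return a new `recall_study` with permuted labels.
#' @export
permute_labels <- function(study, scheme) {
  stopifnot(inherits(study, "recall_study"),
            inherits(scheme, "permutation_scheme"))
  ev <- study$events
  pp <- participants(study)
  if (scheme$swap_group) {
    newg <- sample(pp$group)
    ev$group <- newg[match(ev$participant_id, pp$participant_id)]
  }
  if (scheme$swap_time) {
    flip <- stats::runif(nrow(pp)) < 0.5
    flip_row <- flip[match(ev$participant_id, pp$participant_id)]
    ev$timepoint <- ifelse(flip_row,
                           ifelse(ev$timepoint == "T1", "T2", "T1"),
                           ev$timepoint)
  }
  out <- study
  out$events <- ev[order(ev$participant_id, ev$timepoint, ev$list_id,
                         ev$output_position), , drop = FALSE]
  rownames(out$events) <- NULL
  out
}

## ---- statistics -------------------------------------------------------

.change_from_counts <- function(counts, group) {
  s1 <- .cell_sums(counts, group, "T1")
  s2 <- .cell_sums(counts, group, "T2")
  if (s1[["denominator"]] == 0 || s2[["denominator"]] == 0) {
    abort_undefined(sprintf(
      "change statistic for %s(%s) undefined in group %s: empty cell",
      counts$metric, counts$category, group))
  }
  s2[["numerator"]] / s2[["denominator"]] -
    s1[["numerator"]] / s1[["denominator"]]
}

#' Within-group T1-to-T2 change in a pooled estimate
#'
#' Returns `M(group, T2) - M(group, T1)` where M is the pooled estimate of
#' the given metric and category.
#'
#' @param study a `recall_study`.
#' @param metric one of "pstart", "pstay", "pstop", "pstop_terminal",
#'   "recall_pct".
#' @param category valence category.
#' @param group "MBCT" or "control".
#' @return numeric scalar.
#' @export
change_stat <- function(study, metric, category, group) {
  .change_from_counts(.participant_counts(study, metric, category),
                      match.arg(group, GROUPS))
}

#' Group-by-time interaction statistic (difference of differences)
#'
#' Returns `change_stat(MBCT) - change_stat(control)`: the difference of
#' the two within-group T1-to-T2 changes. This is the permutation analogue
#' of the ANOVA interaction contrast, obtained by subtracting the
#' conditions of interest.
#'
#' @inheritParams change_stat
#' @return numeric scalar.
#' @export
interaction_stat <- function(study, metric, category) {
  counts <- .participant_counts(study, metric, category)
  .change_from_counts(counts, "MBCT") - .change_from_counts(counts, "control")
}

## Vectorized null statistics from per-participant counts.
## Returns B statistics (NaN where a permuted cell is empty).
.null_stats <- function(counts, scheme, B, effect, group = NULL) {
  n <- nrow(counts$N)
  grp <- counts$participants$group
  N1 <- counts$N[, 1]; N2 <- counts$N[, 2]
  D1 <- counts$D[, 1]; D2 <- counts$D[, 2]
  S <- if (scheme$swap_time) {
    matrix(as.numeric(stats::runif(n * B) < 0.5), n, B)
  } else matrix(0, n, B)
  N1e <- N1 * (1 - S) + N2 * S
  N2e <- N1 * S + N2 * (1 - S)
  D1e <- D1 * (1 - S) + D2 * S
  D2e <- D1 * S + D2 * (1 - S)
  M <- if (scheme$swap_group) {
    matrix(vapply(seq_len(B), function(j) sample(grp) == "MBCT",
                  logical(n)), n, B) + 0
  } else matrix(as.numeric(grp == "MBCT"), n, B)
  chg <- function(W) {
    colSums(W * N2e) / colSums(W * D2e) - colSums(W * N1e) / colSums(W * D1e)
  }
  if (effect == "time_within_group") {
    chg(if (group == "MBCT") M else 1 - M)
  } else {
    chg(M) - chg(1 - M)
  }
}

.observed_stat <- function(counts, effect, group) {
  if (effect == "time_within_group") {
    .change_from_counts(counts, group)
  } else {
    .change_from_counts(counts, "MBCT") - .change_from_counts(counts, "control")
  }
}

.pvalue <- function(null, obs, sidedness, add_one = TRUE) {
  eps <- 1e-12
  hits <- switch(sidedness,
                 two_sided = sum(abs(null) >= abs(obs) - eps),
                 greater = sum(null >= obs - eps),
                 less = sum(null <= obs + eps))
  if (add_one) (1 + hits) / (1 + length(null)) else hits / length(null)
}

.result <- function(metric, category, effect, group, obs, null, n_perm,
                    p_value, sidedness, seed, n_redraws = 0L,
                    exhaustive = FALSE) {
  structure(list(metric = metric, category = category, effect = effect,
                 group = group, observed_stat = obs, n_perm = n_perm,
                 p_value = p_value, sidedness = sidedness, seed = seed,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 n_redraws = n_redraws, exhaustive = exhaustive),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s): %s %s%s\n  observed = %+.4f, p = %.4g (%s, %s%d assignments%s)\n",
    x$effect, x$metric, x$category,
    if (!is.null(x$group) && !is.na(x$group)) paste0(", group ", x$group) else "",
    x$observed_stat, x$p_value, x$sidedness,
    if (x$exhaustive) "all " else "", x$n_perm,
    if (x$n_redraws > 0) sprintf(", %d redraws", x$n_redraws) else ""))
  invisible(x)
}

#' Monte-Carlo permutation test for recall-dynamics effects
#'
#' Tests either the within-group T1-to-T2 change (`effect =
#' "time_within_group"`, null built by flipping each participant's time
#' labels) or the group-by-time interaction (`effect = "interaction"`, null
#' built by jointly shuffling group labels across participants and flipping
#' time labels within participants), recomputing the pooled statistic for
#' each of `n_perm` relabelled datasets. The p-value uses add-one
#' smoothing, `p = (1 + #\{|perm| >= |obs|\}) / (1 + n_perm)` for the
#' two-sided default, so it is always positive and valid under Monte-Carlo
#' sampling. Replicates where the permuted statistic is undefined (an empty
#' pooled cell after relabelling) are redrawn, with the redraw count
#' reported; if more than half of the replicates need redrawing the data
#' are considered degenerate and an error is raised.
#'
#' @inheritParams change_stat
#' @param effect "interaction" or "time_within_group".
#' @param group required for `time_within_group`.
#' @param n_perm number of permutations (default 1000).
#' @param sidedness "two_sided" (default), "greater", or "less".
#' @param seed integer seed; identical inputs and seed give identical
#'   results.
#' @return object of class `permutation_result`.
#' @export
permutation_test <- function(study, metric, category,
                             effect = c("interaction", "time_within_group"),
                             group = NULL, n_perm = 1000L,
                             sidedness = c("two_sided", "greater", "less"),
                             seed = NULL) {
  effect <- match.arg(effect)
  sidedness <- match.arg(sidedness)
  if (n_perm < 1) abort_config("n_perm must be >= 1")
  if (effect == "time_within_group") {
    if (is.null(group)) abort_config("time_within_group requires a group")
    group <- match.arg(group, GROUPS)
    scheme <- permutation_scheme(swap_time = TRUE)
  } else {
    group <- NA_character_
    scheme <- permutation_scheme(swap_group = TRUE, swap_time = TRUE)
  }
  counts <- .participant_counts(study, metric, category)
  obs <- .observed_stat(counts, effect, group)
  if (!is.null(seed)) set.seed(seed)
  null <- .null_stats(counts, scheme, n_perm, effect, group)
  n_redraws <- 0L
  while (any(!is.finite(null))) {
    bad <- which(!is.finite(null))
    n_redraws <- n_redraws + length(bad)
    if (n_redraws > n_perm / 2) {
      abort_degenerate(sprintf(
        "more than half of the permutation replicates were undefined for %s(%s)",
        metric, category))
    }
    null[bad] <- .null_stats(counts, scheme, length(bad), effect, group)
  }
  .result(metric, category, effect, group, obs, null, as.integer(n_perm),
          .pvalue(null, obs, sidedness), sidedness,
          seed %||% NA_integer_, n_redraws)
}

#' Exact permutation test by complete enumeration
#'
#' Enumerates every label assignment of the scheme (including the identity)
#' and computes the p-value over the complete enumeration, with no
#' randomness. For `time_within_group` only the time flips of the tested
#' group's participants matter, so 2^k assignments are enumerated; for
#' `interaction` all group relabellings crossed with all time flips are
#' enumerated. A capacity error is raised when the enumeration exceeds
#' `max_assignments`. Intended as the small-sample oracle against which the
#' Monte-Carlo test is validated.
#'
#' @inheritParams permutation_test
#' @param max_assignments enumeration size guard.
#' @return object of class `permutation_result` with `exhaustive = TRUE`.
#' @export
exact_test <- function(study, metric, category,
                       effect = c("interaction", "time_within_group"),
                       group = NULL,
                       sidedness = c("two_sided", "greater", "less"),
                       max_assignments = 200000L) {
  effect <- match.arg(effect)
  sidedness <- match.arg(sidedness)
  counts <- .participant_counts(study, metric, category)
  grp <- counts$participants$group
  n <- length(grp)
  N1 <- counts$N[, 1]; N2 <- counts$N[, 2]
  D1 <- counts$D[, 1]; D2 <- counts$D[, 2]

  flips_matrix <- function(k) {
    m <- 0:(2^k - 1)
    vapply(seq_len(k), function(i) as.numeric(bitwAnd(m, 2^(i - 1)) > 0),
           numeric(length(m)))  # 2^k x k
  }

  if (effect == "time_within_group") {
    if (is.null(group)) abort_config("time_within_group requires a group")
    group <- match.arg(group, GROUPS)
    rows <- which(grp == group)
    k <- length(rows)
    if (2^k > max_assignments) {
      abort_capacity(sprintf("enumeration of 2^%d time flips exceeds cap", k))
    }
    S <- t(flips_matrix(k))                      # k x 2^k
    n1 <- N1[rows]; n2 <- N2[rows]; d1 <- D1[rows]; d2 <- D2[rows]
    stat <- (colSums((n1 * S + n2 * (1 - S))) /
               colSums((d1 * S + d2 * (1 - S)))) -
      (colSums((n1 * (1 - S) + n2 * S)) / colSums((d1 * (1 - S) + d2 * S)))
    group_out <- group
  } else {
    n_mbct <- sum(grp == "MBCT")
    n_assign <- choose(n, n_mbct) * 2^n
    if (n_assign > max_assignments) {
      abort_capacity(sprintf(
        "interaction enumeration needs %.0f assignments (cap %d)",
        n_assign, max_assignments))
    }
    combos <- utils::combn(n, n_mbct)            # n_mbct x C
    C <- ncol(combos)
    M <- matrix(0, n, C)
    M[cbind(as.vector(combos), rep(seq_len(C), each = n_mbct))] <- 1
    S0 <- t(flips_matrix(n))                     # n x 2^n
    A2 <- ncol(S0)
    M <- M[, rep(seq_len(C), times = A2), drop = FALSE]
    S <- S0[, rep(seq_len(A2), each = C), drop = FALSE]
    N1e <- N1 * (1 - S) + N2 * S; N2e <- N1 * S + N2 * (1 - S)
    D1e <- D1 * (1 - S) + D2 * S; D2e <- D1 * S + D2 * (1 - S)
    chg <- function(W) {
      colSums(W * N2e) / colSums(W * D2e) - colSums(W * N1e) / colSums(W * D1e)
    }
    stat <- chg(M) - chg(1 - M)
    group_out <- NA_character_
  }
  obs <- .observed_stat(counts, effect, group_out)
  defined <- is.finite(stat)
  stat <- stat[defined]
  .result(metric, category, effect, group_out, obs, stat, length(stat),
          .pvalue(stat, obs, sidedness, add_one = FALSE), sidedness,
          NA_integer_, n_redraws = sum(!defined), exhaustive = TRUE)
}
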