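## Per-participant, per-timepoint numerator/denominator counts for one
## (metric, category). Every pooled statistic in the package is a ratio of
## sums of these counts over the participants of a design cell, which is
## what makes label permutation cheap: relabelling moves whole rows.
.participant_counts <- function(study, metric, category) {
  metric <- match.arg(metric, c("pstart", "pstay", "pstop",
                                "pstop_terminal", "recall_pct"))
  if (!study$scored) study <- score_study(study)
  pp <- participants(study)
  n <- nrow(pp)
  r <- .retained(study)
  pidx <- match(r$participant_id, pp$participant_id)
  tidx <- match(r$timepoint, TIMEPOINTS)
  cell <- pidx + (tidx - 1L) * n
  tab <- function(mask) {
    matrix(tabulate(cell[mask], nbins = 2L * n), nrow = n, ncol = 2L,
           dimnames = list(pp$participant_id, TIMEPOINTS))
  }
  if (metric == "pstart") {
    N <- tab(r$first & r$category == category)
    D <- tab(r$first)
  } else if (metric == "pstay") {
    m <- nrow(r)
    cons <- if (m > 1) which(r$seq_key[-m] == r$seq_key[-1]) else integer()
    from <- r$category[cons]
    to <- r$category[cons + 1L]
    cell <- cell[cons]
    tab2 <- function(mask) {
      matrix(tabulate(cell[mask], nbins = 2L * n), nrow = n, ncol = 2L,
             dimnames = list(pp$participant_id, TIMEPOINTS))
    }
    N <- tab2(from == category & to == category)
    D <- tab2(from == category)
  } else if (metric == "pstop") {
    N <- tab(r$last & r$category == category)
    D <- tab(r$category == category)
  } else if (metric == "pstop_terminal") {
    N <- tab(r$last & r$category == category)
    D <- tab(r$last)
  } else { # recall_pct
    N <- tab(r$category == category)
    npc <- targets_per_category(study$lists)[[category]]
    D <- matrix(npc * study$lists_per_assessment, nrow = n, ncol = 2L,
                dimnames = list(pp$participant_id, TIMEPOINTS))
  }
  list(participants = pp, N = N, D = D, metric = metric, category = category)
}

.cell_sums <- function(counts, group, timepoint) {
  rows <- counts$participants$group == group
  t <- match(timepoint, TIMEPOINTS)
  c(numerator = sum(counts$N[rows, t]), denominator = sum(counts$D[rows, t]))
}

.estimate_row <- function(counts, group, timepoint, percent = FALSE) {
  s <- .cell_sums(counts, group, timepoint)
  if (s[["denominator"]] == 0) {
    abort_undefined(sprintf(
      "%s(%s) is undefined in cell (%s, %s): zero denominator",
      counts$metric, counts$category, group, timepoint))
  }
  value <- s[["numerator"]] / s[["denominator"]]
  data.frame(metric = counts$metric, category = counts$category,
             group = group, timepoint = timepoint,
             numerator = as.integer(s[["numerator"]]),
             denominator = as.integer(s[["denominator"]]),
             value = if (percent) 100 * value else value,
             stringsAsFactors = FALSE)
}

.pooled_metric <- function(study, metric, group, timepoint,
                           categories = CATEGORIES, percent = FALSE) {
  group <- match.arg(group, GROUPS)
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  out <- lapply(categories, function(cat) {
    .estimate_row(.participant_counts(study, metric, cat), group, timepoint,
                  percent = percent)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pooled probability of first recall (Pstart)
#'
#' For each valence category v, the fraction of lists in the (group,
#' timepoint) cell whose retained recall sequence (targets only) begins
#' with a category-v word. Counts are pooled over all participants and
#' lists in the cell before division; estimates across the three categories
#' sum to 1. Pstart indexes the affective bias of the mental context at
#' recall onset.
#'
#' @param study a `recall_study` (scored automatically if needed).
#' @param group "MBCT" or "control".
#' @param timepoint "T1" or "T2".
#' @param categories categories to report (default all three).
#' @return data.frame of estimates (metric, category, group, timepoint,
#'   numerator, denominator, value).
#' @export
pooled_pstart <- function(study, group, timepoint, categories = CATEGORIES) {
  .pooled_metric(study, "pstart", group, timepoint, categories)
}

#' Pooled stay-vs-switch probability (Pstay)
#'
#' For each valence category v, the fraction of retained transitions
#' originating from a category-v word that land on another category-v word
#' (terminal recalls contribute no transition). Pstay indexes the strength
#' of within-valence association networks. An error of class
#' `rdyn_undefined_error` is raised for a requested category with zero
#' originating transitions in the cell.
#'
#' @inheritParams pooled_pstart
#' @return data.frame of estimates.
#' @export
pooled_pstay <- function(study, group, timepoint, categories = CATEGORIES) {
  .pooled_metric(study, "pstay", group, timepoint, categories)
}

#' Pooled stopping hazard (Pstop)
#'
#' For each valence category v, the probability that a retained category-v
#' recall is the last retained recall of its list: lists ending in v
#' divided by all retained v recalls in the cell. Pstop indexes the
#' persistence ("stickiness") of a valenced mental context at the end of
#' recall. For the terminal-share reading (lists ending in v over all
#' nonempty lists) see [terminal_category_distribution()].
#'
#' @inheritParams pooled_pstart
#' @return data.frame of estimates.
#' @export
pooled_pstop <- function(study, group, timepoint, categories = CATEGORIES) {
  .pooled_metric(study, "pstop", group, timepoint, categories)
}

#' Distribution of the terminal recall category
#'
#' The alternative reading of stopping behaviour: for each category v, the
#' fraction of nonempty retained lists in the cell whose final retained
#' recall is category v. Sums to 1 across categories.
#'
#' @inheritParams pooled_pstart
#' @return data.frame of estimates.
#' @export
terminal_category_distribution <- function(study, group, timepoint,
                                           categories = CATEGORIES) {
  .pooled_metric(study, "pstop_terminal", group, timepoint, categories)
}

#' Per-valence percentage of words recalled
#'
#' For each category v, distinct category-v targets recalled (repetitions
#' are excluded by scoring) summed over lists, divided by the number of
#' presented category-v targets (targets per category times lists per
#' assessment times participants in the cell), on the percent scale. Lists
#' recalled empty still count in the denominator.
#'
#' @inheritParams pooled_pstart
#' @return data.frame of estimates (value in percent).
#' @export
recall_percentage <- function(study, group, timepoint,
                              categories = CATEGORIES) {
  pp <- participants(study)
  if (!any(pp$group == group)) {
    abort_undefined(sprintf("no participants in cell (%s, %s)",
                            group, timepoint))
  }
  .pooled_metric(study, "recall_pct", group, timepoint, categories,
                 percent = TRUE)
}

#' All pooled estimates for every design cell
#'
#' Convenience wrapper computing every metric for every (group, timepoint)
#' cell; cells where a metric is undefined yield rows with NA value and
#' counts, rather than an error.
#'
#' @param study a `recall_study`.
#' @param metrics which metrics to compute.
#' @return data.frame of estimates with one row per metric x category x
#'   group x timepoint.
#' @export
dynamics_table <- function(study,
                           metrics = c("pstart", "pstay", "pstop",
                                       "pstop_terminal", "recall_pct")) {
  if (!study$scored) study <- score_study(study)
  rows <- list()
  for (metric in metrics) {
    for (cat in CATEGORIES) {
      counts <- .participant_counts(study, metric, cat)
      for (g in GROUPS) {
        for (t in TIMEPOINTS) {
          row <- tryCatch(
            .estimate_row(counts, g, t, percent = metric == "recall_pct"),
            rdyn_undefined_error = function(e) {
              data.frame(metric = metric, category = cat, group = g,
                         timepoint = t, numerator = NA_integer_,
                         denominator = NA_integer_, value = NA_real_,
                         stringsAsFactors = FALSE)
            })
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
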