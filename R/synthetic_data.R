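#' Parameters of the category-level Markov recall model
#'
#' The generative stand-in for recall dynamics: recall starts in a valence
#' category drawn from `start_probs`, each recalled word is drawn uniformly
#' without replacement from the unrecalled targets of the current category,
#' recall stops after a category-c word with probability `stop_hazard[c]`,
#' and otherwise the next category is drawn from row c of `stay_switch`.
#' When a category runs out of unrecalled targets it is removed and the
#' remaining probabilities are renormalized (item depletion). This is a
#' category-level approximation of retrieved-context models (TCM/CMR): it
#' is the minimal process for which Pstart, Pstay and Pstop are sufficient
#' descriptions.
#'
#' @param start_probs probability vector over (positive, negative, neutral);
#'   must sum to 1.
#' @param stay_switch 3x3 row-stochastic matrix of category-to-category
#'   transition probabilities, conditional on not stopping; rows/cols in
#'   (positive, negative, neutral) order.
#' @param stop_hazard per-category stopping probabilities in [0, 1).
#' @param max_recalls cap on sequence length (default 22).
#' @return object of class `markov_params`.
#' @export
markov_params <- function(start_probs = c(positive = 0.30, negative = 0.40,
                                          neutral = 0.30),
                          stay_switch = matrix(c(0.30, 0.35, 0.35,
                                                 0.35, 0.30, 0.35,
                                                 0.35, 0.35, 0.30),
                                               3, 3, byrow = TRUE),
                          stop_hazard = c(positive = 0.12, negative = 0.12,
                                          neutral = 0.12),
                          max_recalls = 22L) {
  start_probs <- stats::setNames(as.numeric(start_probs), CATEGORIES)
  stop_hazard <- stats::setNames(as.numeric(stop_hazard), CATEGORIES)
  stay_switch <- matrix(as.numeric(stay_switch), 3, 3,
                        dimnames = list(CATEGORIES, CATEGORIES))
  if (abs(sum(start_probs) - 1) > 1e-8 || any(start_probs < 0)) {
    abort_config("start_probs must be a probability vector summing to 1")
  }
  if (any(abs(rowSums(stay_switch) - 1) > 1e-8) || any(stay_switch < 0)) {
    abort_config("each stay_switch row must be a probability vector")
  }
  if (any(stop_hazard < 0 | stop_hazard >= 1)) {
    abort_config("stop hazards must lie in [0, 1)")
  }
  if (max_recalls < 1) abort_config("max_recalls must be positive")
  structure(list(start_probs = start_probs, stay_switch = stay_switch,
                 stop_hazard = stop_hazard,
                 max_recalls = as.integer(max_recalls)),
            class = "markov_params")
}

## category-index sequence from the Markov model; navail = items per
## category. Uses the current RNG state; plain runif-based draws keep the
## per-recall cost minimal.
.sim_category_seq <- function(params, navail) {
  k <- navail
  if (sum(k) == 0) abort_capacity("stimulus list has zero targets")
  out <- integer(min(sum(k), params$max_recalls))
  w <- params$start_probs * (k > 0)
  cat <- findInterval(stats::runif(1) * sum(w), cumsum(w)) + 1L
  len <- 0L
  repeat {
    len <- len + 1L
    out[len] <- cat
    k[cat] <- k[cat] - 1L
    if (len >= params$max_recalls || sum(k) == 0) break
    if (stats::runif(1) < params$stop_hazard[[cat]]) break
    w <- params$stay_switch[cat, ] * (k > 0)
    s <- sum(w)
    if (s == 0) break
    cat <- findInterval(stats::runif(1) * s, cumsum(w)) + 1L
  }
  out[seq_len(len)]
}

#' Simulate one recall sequence from the category-Markov model
#'
#' Generates a recall sequence for a stimulus list: only target events are
#' produced (no intrusions, repetitions, or buffer recalls) unless
#' `intrusion_rate` / `repetition_rate` are set, which inject such events
#' purely to exercise the scoring pipeline. Items within a category are
#' drawn uniformly without replacement. Uses the current RNG state.
#'
#' @param params a [markov_params()].
#' @param stim a `stimulus_lists` table for a single list.
#' @param intrusion_rate,repetition_rate per-position probabilities of
#'   inserting a non-list word or an already-recalled word after each
#'   genuine recall (defaults 0).
#' @return character vector of recalled words, in output order.
#' @export
simulate_recall <- function(params, stim, intrusion_rate = 0,
                            repetition_rate = 0) {
  stopifnot(inherits(params, "markov_params"))
  stim <- if (inherits(stim, "stimulus_lists")) stim else stimulus_lists(stim)
  targets <- split(stim$word[!stim$is_buffer],
                   factor(stim$category[!stim$is_buffer], CATEGORIES))
  cats <- .sim_category_seq(params, vapply(targets, length, integer(1)))
  ## uniform without replacement within category = a pre-shuffled order
  pools <- lapply(targets, sample)
  taken <- c(0L, 0L, 0L)
  words <- character(length(cats))
  for (i in seq_along(cats)) {
    taken[cats[i]] <- taken[cats[i]] + 1L
    words[i] <- pools[[cats[i]]][taken[cats[i]]]
  }
  if (intrusion_rate > 0 || repetition_rate > 0) {
    out <- character(0)
    for (w in words) {
      out <- c(out, w)
      if (stats::runif(1) < intrusion_rate) {
        out <- c(out, paste0("xx", paste(sample(letters, 5, TRUE),
                                         collapse = "")))
      }
      if (length(out) > 1 && stats::runif(1) < repetition_rate) {
        out <- c(out, sample(out[seq_len(length(out) - 1)], 1))
      }
    }
    words <- out
  }
  words
}

#' Block randomization of trial arms
#'
#' Assigns `n_total` participants to MBCT vs. control block by block with
#' block size 5 and a 3:2 ratio by default: each complete block contains
#' exactly `ratio[1]` MBCT and `ratio[2]` control labels in uniformly
#' random order, and a final partial block is a uniform draw without
#' replacement from a fresh block's labels. Uses the current RNG state.
#'
#' @param n_total number of assignments.
#' @param block_size block size (default 5).
#' @param ratio integer pair (MBCT, control) summing to `block_size`.
#' @return character vector of group labels in allocation order.
#' @export
block_randomize <- function(n_total, block_size = 5L, ratio = c(3L, 2L)) {
  if (sum(ratio) != block_size) {
    abort_config("ratio components must sum to block_size")
  }
  block <- rep(GROUPS, times = ratio)
  n_blocks <- ceiling(n_total / block_size)
  out <- unlist(lapply(seq_len(n_blocks), function(i) sample(block)))
  out[seq_len(n_total)]
}

#' Design of a simulated two-arm, two-timepoint recall trial
#'
#' @param n_mbct,n_control arm sizes (defaults 29 and 23).
#' @param lists_per_assessment lists recalled per participant per timepoint
#'   (default 3).
#' @param list_spec a [list_spec()] used to build the stimulus lists.
#' @param cell_params named list of [markov_params()] for the four design
#'   cells: `MBCT.T1`, `MBCT.T2`, `control.T1`, `control.T2`.
#' @param seed integer seed; the simulated trial is fully deterministic
#'   given the design.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(n_mbct = 29L, n_control = 23L,
                         lists_per_assessment = 3L,
                         list_spec = recalldyn::list_spec(),
                         cell_params = null_cell_params(),
                         seed = 1L) {
  if (n_mbct < 1 || n_control < 1) {
    abort_config("arm sizes must be positive")
  }
  needed <- as.vector(outer(GROUPS, TIMEPOINTS, paste, sep = "."))
  if (!all(needed %in% names(cell_params))) {
    abort_config(sprintf("cell_params must name all of: %s",
                         paste(needed, collapse = ", ")))
  }
  for (p in cell_params[needed]) stopifnot(inherits(p, "markov_params"))
  structure(list(n_mbct = as.integer(n_mbct),
                 n_control = as.integer(n_control),
                 lists_per_assessment = as.integer(lists_per_assessment),
                 list_spec = list_spec, cell_params = cell_params,
                 seed = as.integer(seed)),
            class = "trial_design")
}

#' Identical generative parameters in all four design cells (null design)
#'
#' @param base a [markov_params()] shared by every cell.
#' @return named list of cell parameters for [trial_design()].
#' @export
null_cell_params <- function(base = markov_params()) {
  out <- list(base, base, base, base)
  names(out) <- as.vector(outer(GROUPS, TIMEPOINTS, paste, sep = "."))
  out
}

## shift a stay-switch row's diagonal by d, rescaling the off-diagonal mass
.shift_diag <- function(stay, cat, d) {
  i <- match(cat, CATEGORIES)
  new_diag <- min(max(stay[i, i] + d, 0.02), 0.96)
  off <- stay[i, -i]
  stay[i, -i] <- off / sum(off) * (1 - new_diag)
  stay[i, i] <- new_diag
  stay
}

#' Cell parameters planting the reported direction of treatment effects
#'
#' Encodes the qualitative group-by-time pattern of the reference findings
#' as T1-to-T2 parameter drifts of magnitude `effect`: in the MBCT cells
#' the negative stay-switch diagonal goes down and the positive diagonal
#' up, and the negative stopping hazard goes down; in the control cells the
#' stay drifts are reversed. T1 cells share `base` in both arms.
#'
#' @param effect drift magnitude on the probability scale (default 0.15).
#' @param base T1 [markov_params()] for both arms.
#' @return named list of cell parameters for [trial_design()].
#' @export
effect_cell_params <- function(effect = 0.15, base = markov_params()) {
  mbct_t2 <- base
  mbct_t2$stay_switch <- .shift_diag(.shift_diag(base$stay_switch,
                                                 "negative", -effect),
                                     "positive", +effect)
  mbct_t2$stop_hazard["negative"] <-
    max(base$stop_hazard[["negative"]] - effect, 0.01)
  ctrl_t2 <- base
  ctrl_t2$stay_switch <- .shift_diag(.shift_diag(base$stay_switch,
                                                 "negative", +effect),
                                     "positive", -effect)
  list(MBCT.T1 = base, MBCT.T2 = mbct_t2,
       control.T1 = base, control.T2 = ctrl_t2)
}

#' Simulate a full two-arm, two-timepoint recall trial
#'
#' Produces a `recall_study` with `n_mbct + n_control` participants, each
#' recalling `lists_per_assessment` lists at T1 and again (from a disjoint
#' counterbalanced list set) at T2, generated from the corresponding cell's
#' Markov parameters. Stimulus lists are built by [build_list_sets()] from
#' `norms` unless pre-built `lists` are supplied. Fully deterministic given
#' `design$seed` (per-participant RNG substreams are derived from it).
#'
#' @param design a [trial_design()].
#' @param norms word-norms table (default [synthetic_word_norms()]).
#' @param lists optional pre-built list sets (a named list of
#'   `stimulus_lists` as returned by [build_list_sets()], `set1` used at T1
#'   and `set2` at T2); when supplied, list construction is skipped.
#' @param intrusion_rate,repetition_rate see [simulate_recall()].
#' @return a scored `recall_study`.
#' @export
simulate_trial <- function(design, norms = synthetic_word_norms(),
                           lists = NULL, intrusion_rate = 0,
                           repetition_rate = 0) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(design$seed)
  if (is.null(lists)) {
    lists <- build_list_sets(norms, design$list_spec,
                             n_lists = design$lists_per_assessment,
                             n_sets = 2L)
  }
  take <- function(s) {
    keep <- unique(s$list_id)[seq_len(design$lists_per_assessment)]
    if (anyNA(keep)) abort_capacity("supplied list sets have too few lists")
    s[s$list_id %in% keep, , drop = FALSE]
  }
  set_for_time <- list(T1 = take(lists$set1), T2 = take(lists$set2))
  n <- design$n_mbct + design$n_control
  pids <- sprintf("P%03d", seq_len(n))
  groups <- rep(GROUPS, times = c(design$n_mbct, design$n_control))
  pseeds <- sample.int(.Machine$integer.max - 1L, n)

  ## pre-extract per-list target pools; the per-sequence work is then just
  ## the Markov draw plus a within-category shuffle
  by_list <- lapply(set_for_time, function(s) {
    lapply(split(as.data.frame(s), s$list_id), function(lst) {
      list(id = lst$list_id[1], full = lst,
           targets = split(lst$word[!lst$is_buffer],
                           factor(lst$category[!lst$is_buffer], CATEGORIES)))
    })
  })
  inject <- intrusion_rate > 0 || repetition_rate > 0
  n_seq <- n * 2L * design$lists_per_assessment
  seq_words <- vector("list", n_seq)
  seq_p <- integer(n_seq); seq_tp <- character(n_seq)
  seq_lid <- character(n_seq)
  i <- 0L
  for (p in seq_len(n)) {
    set.seed(pseeds[p])
    for (tp in TIMEPOINTS) {
      params <- design$cell_params[[paste(groups[p], tp, sep = ".")]]
      for (lst in by_list[[tp]]) {
        words <- if (inject) {
          simulate_recall(params, lst$full, intrusion_rate, repetition_rate)
        } else {
          cats <- .sim_category_seq(
            params, vapply(lst$targets, length, integer(1)))
          pools <- lapply(lst$targets, sample)
          taken <- c(0L, 0L, 0L)
          w <- character(length(cats))
          for (j in seq_along(cats)) {
            taken[cats[j]] <- taken[cats[j]] + 1L
            w[j] <- pools[[cats[j]]][taken[cats[j]]]
          }
          w
        }
        i <- i + 1L
        seq_words[[i]] <- words
        seq_p[i] <- p; seq_tp[i] <- tp; seq_lid[i] <- lst$id
      }
    }
  }
  lens <- lengths(seq_words)
  events <- data.frame(
    participant_id = rep(pids[seq_p], lens),
    group = rep(groups[seq_p], lens),
    timepoint = rep(seq_tp, lens),
    list_id = rep(seq_lid, lens),
    output_position = unlist(lapply(lens, seq_len)),
    word = unlist(seq_words),
    stringsAsFactors = FALSE)
  all_lists <- rbind(as.data.frame(lists$set1), as.data.frame(lists$set2))
  score_study(recall_study(events, all_lists,
                           lists_per_assessment = design$lists_per_assessment))
}

#' Monte-Carlo expectation of the pooled dynamics under given parameters
#'
#' Simulates `n_mc` recall sequences from the category-Markov model on a
#' list of the given composition and computes the pooled Pstart, Pstay and
#' Pstop per category. Serves as the reference value for parameter-recovery
#' checks under item depletion (where pooled metrics need not equal the raw
#' parameters).
#'
#' @param params a [markov_params()].
#' @param n_per_category targets per category of the simulated list.
#' @param n_mc number of simulated sequences.
#' @param seed integer seed.
#' @return data.frame with columns metric, category, value.
#' @export
expected_metrics_oracle <- function(params, n_per_category = 6L,
                                    n_mc = 10000L, seed = 1L) {
  if (n_mc < 1) abort_config("n_mc must be >= 1")
  set.seed(seed)
  navail <- rep(as.integer(n_per_category), 3)
  first <- integer(3); starts <- 0L
  stay_n <- integer(3); stay_d <- integer(3)
  last <- integer(3); recalls <- integer(3)
  for (i in seq_len(n_mc)) {
    s <- .sim_category_seq(params, navail)
    m <- length(s)
    first[s[1]] <- first[s[1]] + 1L
    starts <- starts + 1L
    last[s[m]] <- last[s[m]] + 1L
    recalls <- recalls + tabulate(s, 3)
    if (m > 1) {
      from <- s[-m]; to <- s[-1]
      stay_d <- stay_d + tabulate(from, 3)
      stay_n <- stay_n + tabulate(from[from == to], 3)
    }
  }
  data.frame(
    metric = rep(c("pstart", "pstay", "pstop"), each = 3),
    category = rep(CATEGORIES, 3),
    value = c(first / starts, stay_n / stay_d, last / recalls),
    stringsAsFactors = FALSE)
}
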