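#' Specification for affective stimulus lists
#'
#' Captures the composition, selection-window, mean-target, and balance
#' constraints a stimulus list must satisfy: 22 words per list made of 6
#' positive, 6 negative and 6 neutral targets plus 4 neutral buffers at the
#' list edges; no two consecutive targets share a valence category; per-list
#' category means near the normative targets; and between-list balance of
#' valence, arousal, word length and log frequency.
#'
#' @param n_per_category targets per valence category (default 6).
#' @param n_buffers neutral buffer words per list (default 4).
#' @param total_length list length (must equal `3 * n_per_category +
#'   n_buffers`; default 22).
#' @param windows named list (positive/negative/neutral) of inclusive
#'   selection windows `c(valence_lo, valence_hi, arousal_lo, arousal_hi)`.
#'   The valence windows must be disjoint between categories. Defaults are
#'   roughly mean +/- 2 SD of the normative targets.
#' @param target_means named list of per-category `c(valence, arousal)`
#'   targets for the list means.
#' @param target_tolerance max allowed deviation of a per-list category mean
#'   from its target (rating units).
#' @param balance_tolerance named vector: max allowed between-list range of
#'   target-word means for valence, arousal, length (characters) and
#'   log_frequency (natural log occurrences/million).
#' @param n_list_sets number of disjoint counterbalanced list sets built by
#'   [build_list_sets()] (default 2: one per assessment).
#' @param buffer_split integer pair: buffers placed at the start and end of
#'   the list (default `c(2, 2)`).
#' @param order_includes_buffers if TRUE the no-consecutive-same-category
#'   constraint also spans buffer items; default FALSE (buffers are neutral
#'   and excluded from analysis, and including them can make a neutral
#'   target adjacent to a buffer unsatisfiable).
#' @param max_order_tries retry cap for the shuffle-until-valid ordering
#'   search.
#' @return object of class `list_spec`.
#' @export
list_spec <- function(n_per_category = 6L,
                      n_buffers = 4L,
                      total_length = 3L * n_per_category + n_buffers,
                      windows = list(
                        positive = c(6.7, 9.0, 4.2, 7.4),
                        negative = c(1.0, 4.1, 2.7, 8.3),
                        neutral  = c(4.5, 5.9, 2.9, 4.8)),
                      target_means = list(
                        positive = c(valence = 7.50, arousal = 5.80),
                        negative = c(valence = 2.60, arousal = 5.50),
                        neutral  = c(valence = 5.18, arousal = 3.84)),
                      target_tolerance = 0.5,
                      balance_tolerance = c(valence = 0.5, arousal = 0.6,
                                            length = 1.5,
                                            log_frequency = 0.9),
                      n_list_sets = 2L,
                      buffer_split = c(2L, 2L),
                      order_includes_buffers = FALSE,
                      max_order_tries = 10000L) {
  if (total_length != 3L * n_per_category + n_buffers) {
    abort_config(sprintf(
      "total_length (%d) must equal 3*n_per_category + n_buffers (%d)",
      total_length, 3L * n_per_category + n_buffers))
  }
  if (sum(buffer_split) != n_buffers) {
    abort_config("buffer_split must sum to n_buffers")
  }
  ## valence windows must be disjoint so categories cannot overlap
  vw <- lapply(windows, function(w) w[1:2])
  pairs <- utils::combn(names(vw), 2, simplify = FALSE)
  for (p in pairs) {
    a <- vw[[p[1]]]; b <- vw[[p[2]]]
    if (max(a[1], b[1]) <= min(a[2], b[2])) {
      abort_config(sprintf("valence windows for %s and %s overlap",
                           p[1], p[2]))
    }
  }
  structure(list(n_per_category = as.integer(n_per_category),
                 n_buffers = as.integer(n_buffers),
                 total_length = as.integer(total_length),
                 windows = windows, target_means = target_means,
                 target_tolerance = target_tolerance,
                 balance_tolerance = balance_tolerance,
                 n_list_sets = as.integer(n_list_sets),
                 buffer_split = as.integer(buffer_split),
                 order_includes_buffers = isTRUE(order_includes_buffers),
                 max_order_tries = as.integer(max_order_tries)),
            class = "list_spec")
}

.eligible <- function(norms, spec, category, exclude = character()) {
  w <- spec$windows[[category]]
  ok <- norms$valence >= w[1] & norms$valence <= w[2] &
    norms$arousal >= w[3] & norms$arousal <= w[4] &
    !(norms$word %in% exclude)
  which(ok)
}

## scalar violation score of an assignment; 0 means all constraints met
.assignment_score <- function(norms, spec, sel, list_of) {
  n_lists <- max(list_of[[1]])
  viol <- 0
  per_list_rows <- vector("list", n_lists)
  for (cat in CATEGORIES) {
    tgt <- spec$target_means[[cat]]
    for (l in seq_len(n_lists)) {
      rows <- sel[[cat]][list_of[[cat]] == l]
      per_list_rows[[l]] <- c(per_list_rows[[l]], rows)
      viol <- viol +
        max(0, abs(mean(norms$valence[rows]) - tgt["valence"]) -
              spec$target_tolerance) +
        max(0, abs(mean(norms$arousal[rows]) - tgt["arousal"]) -
              spec$target_tolerance)
    }
  }
  bt <- spec$balance_tolerance
  feat <- function(rows, dim) switch(dim,
    valence = mean(norms$valence[rows]),
    arousal = mean(norms$arousal[rows]),
    length = mean(norms$length[rows]),
    log_frequency = mean(log(norms$frequency[rows] + 1e-6)))
  for (dim in names(bt)) {
    m <- vapply(per_list_rows, feat, numeric(1), dim = dim)
    viol <- viol + max(0, (max(m) - min(m)) - bt[[dim]])
  }
  viol
}

## order 18 target categories with no two consecutive repeats
.order_targets <- function(categories, max_tries) {
  n <- length(categories)
  for (i in seq_len(max_tries)) {
    perm <- sample.int(n)
    if (!any(categories[perm][-1] == categories[perm][-n])) return(perm)
  }
  abort_constraint(sprintf(
    "could not order targets without consecutive same-category words in %d tries",
    max_tries))
}

#' Build balanced affective stimulus lists
#'
#' Selects target and buffer words from a norms table and arranges them into
#' `n_lists` lists satisfying the composition, ordering, per-category mean,
#' and between-list balance constraints of `spec`. Construction is stratified
#' sampling per category followed by greedy swap repair against the balance
#' constraints, then shuffle-until-valid ordering; everything is
#' deterministic given `seed`. Words are never reused across the lists of
#' one call.
#'
#' @param norms word-norms table (see [validate_word_norms()]).
#' @param spec a [list_spec()].
#' @param n_lists number of lists to build.
#' @param seed integer seed.
#' @param exclude_words words that must not be used (e.g. from a previously
#'   built counterbalanced set).
#' @param list_ids optional character ids, default "L01", "L02", ...
#' @return a `stimulus_lists` table covering all `n_lists` lists.
#' @export
build_stimulus_lists <- function(norms, spec = list_spec(), n_lists = 3L,
                                 seed = NULL, exclude_words = character(),
                                 list_ids = NULL) {
  norms <- validate_word_norms(norms)
  if (!is.null(seed)) set.seed(seed)
  npc <- spec$n_per_category
  if (is.null(list_ids)) list_ids <- sprintf("L%02d", seq_len(n_lists))

  elig <- lapply(stats::setNames(CATEGORIES, CATEGORIES), .eligible,
                 norms = norms, spec = spec, exclude = exclude_words)
  need <- stats::setNames(rep(n_lists * npc, 3), CATEGORIES)
  need["neutral"] <- need["neutral"] + n_lists * spec$n_buffers
  for (cat in CATEGORIES) {
    if (length(elig[[cat]]) < need[[cat]]) {
      abort_capacity(sprintf(
        "norms table has %d eligible %s words; %d required",
        length(elig[[cat]]), cat, need[[cat]]))
    }
  }

  list_of <- lapply(stats::setNames(CATEGORIES, CATEGORIES),
                    function(cat) rep(seq_len(n_lists), each = npc))
  best <- NULL
  for (restart in 1:25) {
    sel <- lapply(stats::setNames(CATEGORIES, CATEGORIES),
                  function(cat) sample(elig[[cat]], n_lists * npc))
    score <- .assignment_score(norms, spec, sel, list_of)
    tries <- 0L
    while (score > 0 && tries < 4000L) {
      tries <- tries + 1L
      cat <- sample(CATEGORIES, 1)
      cand <- sel
      if (n_lists > 1 && stats::runif(1) < 0.5) {
        ## swap two same-category words between lists
        i <- sample(length(cand[[cat]]), 2)
        if (list_of[[cat]][i[1]] == list_of[[cat]][i[2]]) next
        cand[[cat]][i] <- cand[[cat]][rev(i)]
      } else {
        ## replace a selected word with an unused eligible word
        unused <- setdiff(elig[[cat]], cand[[cat]])
        if (!length(unused)) next
        cand[[cat]][sample(length(cand[[cat]]), 1)] <-
          unused[sample(length(unused), 1)]
      }
      new_score <- .assignment_score(norms, spec, cand, list_of)
      if (new_score < score) {
        sel <- cand
        score <- new_score
      }
    }
    if (score == 0) { best <- sel; break }
    if (is.null(best) || score < attr(best, "score") %||% Inf) {
      attr(sel, "score") <- score
      best <- sel
    }
  }
  if (is.null(best) || (attr(best, "score") %||% 0) > 0) {
    abort_constraint(sprintf(
      paste("stimulus-list balance constraints unsatisfied after 25 restarts",
            "(residual violation %.3f); relax target_tolerance or",
            "balance_tolerance, or enlarge the norms table"),
      attr(best, "score")))
  }
  sel <- best

  ## buffers: neutral, disjoint from all selected targets
  buffer_pool <- setdiff(elig$neutral, sel$neutral)
  buffers <- sample(buffer_pool, n_lists * spec$n_buffers)

  out <- vector("list", n_lists)
  for (l in seq_len(n_lists)) {
    rows <- unlist(lapply(CATEGORIES,
                          function(cat) sel[[cat]][list_of[[cat]] == l]))
    cats <- rep(CATEGORIES, each = npc)
    buf <- buffers[seq.int((l - 1) * spec$n_buffers + 1, l * spec$n_buffers)]
    if (spec$order_includes_buffers) {
      ## order the full list; buffers pinned at the edges, so just retry
      ## whole-target orderings until edges also satisfy the constraint
      repeat {
        perm <- .order_targets(cats, spec$max_order_tries)
        full_cats <- c(rep("neutral", spec$buffer_split[1]), cats[perm],
                       rep("neutral", spec$buffer_split[2]))
        if (!any(full_cats[-1] == full_cats[-length(full_cats)])) break
      }
    } else {
      perm <- .order_targets(cats, spec$max_order_tries)
    }
    words <- c(norms$word[buf[seq_len(spec$buffer_split[1])]],
               norms$word[rows][perm],
               norms$word[buf[spec$buffer_split[1] + seq_len(spec$buffer_split[2])]])
    categories <- c(rep("neutral", spec$buffer_split[1]), cats[perm],
                    rep("neutral", spec$buffer_split[2]))
    is_buffer <- c(rep(TRUE, spec$buffer_split[1]),
                   rep(FALSE, length(perm)),
                   rep(TRUE, spec$buffer_split[2]))
    out[[l]] <- data.frame(list_id = list_ids[l],
                           serial_position = seq_along(words),
                           word = words, category = categories,
                           is_buffer = is_buffer,
                           stringsAsFactors = FALSE)
  }
  stimulus_lists(do.call(rbind, out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build counterbalanced sets of stimulus lists
#'
#' Builds `n_sets` word-disjoint sets of `n_lists` lists each (default two
#' sets: one administered before and one after treatment, mirroring
#' counterbalanced pre/post list sets).
#'
#' @inheritParams build_stimulus_lists
#' @param n_sets number of sets; default `spec$n_list_sets`.
#' @return named list `set1`, `set2`, ... of `stimulus_lists` tables.
#' @export
build_list_sets <- function(norms, spec = list_spec(), n_lists = 3L,
                            n_sets = spec$n_list_sets, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sets <- vector("list", n_sets)
  used <- character()
  for (s in seq_len(n_sets)) {
    sets[[s]] <- build_stimulus_lists(
      norms, spec, n_lists, seed = NULL, exclude_words = used,
      list_ids = sprintf("S%dL%02d", s, seq_len(n_lists)))
    used <- c(used, sets[[s]]$word)
  }
  names(sets) <- paste0("set", seq_len(n_sets))
  sets
}

#' Validate stimulus lists against a specification
#'
#' Runs each constraint as an independent check and reports pass/fail per
#' check and list; it never raises on a failed check. Mean and balance
#' checks require `norms`; balance is evaluated across all lists present in
#' `lists` (target words only) and is skipped when only one list is given.
#'
#' @param lists a `stimulus_lists` table (one or more lists).
#' @param spec a [list_spec()].
#' @param norms optional word-norms table for mean/balance checks; an error
#'   of class `rdyn_lookup_error` is raised if a list word is absent.
#' @return data.frame with columns check, list_id, pass, detail.
#' @export
validate_stimulus_list <- function(lists, spec = list_spec(), norms = NULL) {
  lists <- if (inherits(lists, "stimulus_lists")) lists else stimulus_lists(lists)
  res <- list()
  add <- function(check, list_id, pass, detail = "") {
    res[[length(res) + 1]] <<- data.frame(
      check = check, list_id = list_id, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  ids <- unique(lists$list_id)
  for (lid in ids) {
    x <- lists[lists$list_id == lid, , drop = FALSE]
    tg <- x[!x$is_buffer, , drop = FALSE]
    comp_ok <- nrow(x) == spec$total_length &&
      sum(x$is_buffer) == spec$n_buffers &&
      all(table(factor(tg$category, CATEGORIES)) == spec$n_per_category)
    add("composition", lid, comp_ok,
        sprintf("%d words, %d buffers, targets %s", nrow(x),
                sum(x$is_buffer),
                paste(table(factor(tg$category, CATEGORIES)), collapse = "/")))
    head_ok <- all(x$is_buffer[seq_len(spec$buffer_split[1])])
    tail_ok <- all(x$is_buffer[nrow(x) - seq_len(spec$buffer_split[2]) + 1])
    neutral_ok <- all(x$category[x$is_buffer] == "neutral")
    add("buffer_placement", lid, head_ok && tail_ok && neutral_ok)
    ord_cats <- if (spec$order_includes_buffers) x$category else tg$category
    ord_ok <- !any(ord_cats[-1] == ord_cats[-length(ord_cats)])
    add("ordering", lid, ord_ok)
    if (!is.null(norms)) {
      norms <- validate_word_norms(norms)
      miss <- setdiff(x$word, norms$word)
      if (length(miss)) {
        abort_lookup(sprintf("list '%s' word(s) missing from norms: %s",
                             lid, paste(miss, collapse = ", ")))
      }
      mean_ok <- TRUE; details <- character()
      for (cat in CATEGORIES) {
        rows <- match(tg$word[tg$category == cat], norms$word)
        dv <- abs(mean(norms$valence[rows]) -
                    spec$target_means[[cat]]["valence"])
        da <- abs(mean(norms$arousal[rows]) -
                    spec$target_means[[cat]]["arousal"])
        if (dv > spec$target_tolerance || da > spec$target_tolerance) {
          mean_ok <- FALSE
        }
        details <- c(details, sprintf("%s dV=%.2f dA=%.2f", cat, dv, da))
      }
      add("category_means", lid, mean_ok, paste(details, collapse = "; "))
    }
  }
  if (!is.null(norms) && length(ids) > 1) {
    tg <- lists[!lists$is_buffer, , drop = FALSE]
    rows <- match(tg$word, norms$word)
    feats <- data.frame(valence = norms$valence[rows],
                        arousal = norms$arousal[rows],
                        length = norms$length[rows],
                        log_frequency = log(norms$frequency[rows] + 1e-6))
    bal_ok <- TRUE; details <- character()
    for (dim in names(spec$balance_tolerance)) {
      m <- tapply(feats[[dim]], tg$list_id, mean)
      rng <- max(m) - min(m)
      if (rng > spec$balance_tolerance[[dim]]) bal_ok <- FALSE
      details <- c(details, sprintf("%s range=%.2f", dim, rng))
    }
    add("balance", "(all)", bal_ok, paste(details, collapse = "; "))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
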