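#' recalldyn: valence-conditioned free recall dynamics
#'
#' Analysis of emotional free recall in two-arm (MBCT vs. wait-list control),
#' two-timepoint (T1/T2) trials: pooled recall-dynamics statistics
#' (probability of first recall, stay-vs-switch transition probability, and
#' per-recall stopping hazard, each conditioned on valence category),
#' per-valence recall percentages, and permutation analogues of ANOVA for
#' within-group change and the group-by-time interaction. A constrained
#' stimulus-list builder, a category-level Markov recall simulator, and an
#' end-to-end pipeline make the whole analysis runnable on synthetic trials.
#'
#' @keywords internal
"_PACKAGE"

## Fixed vocabularies of the design. Timepoints are coded "T1" (pre) and
## "T2" (post); groups are the trial arms.
CATEGORIES <- c("positive", "negative", "neutral")
TIMEPOINTS <- c("T1", "T2")
GROUPS <- c("MBCT", "control")

EVENT_COLS <- c("participant_id", "group", "timepoint", "list_id",
                "output_position", "word")
LIST_COLS <- c("list_id", "serial_position", "word", "category", "is_buffer")

#' Normalize a word for exact matching
#'
#' Lowercases, trims surrounding whitespace, and strips ASCII punctuation.
#' No stemming or fuzzy matching is applied: scoring is exact and therefore
#' reproducible.
#'
#' @param x character vector.
#' @return character vector of normalized words.
#' @export
#' @examples
#' normalize_word(c("  Misery!", "SUN-SHINE "))
normalize_word <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[!\"#$%&'()*+,./:;<=>?@\\[\\\\\\]^_`{|}~-]", "", x, perl = TRUE)
}

.check_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_schema(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
}

.check_values <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad)) {
    abort_schema(sprintf("%s contains value(s) outside {%s}: %s",
                         what, paste(allowed, collapse = ", "),
                         paste(bad, collapse = ", ")))
  }
}

## ---- stimulus lists ---------------------------------------------------

#' Construct/validate a stimulus-list table
#'
#' A stimulus-list table holds one row per presented word with columns
#' `list_id`, `serial_position`, `word`, `category`
#' (positive/negative/neutral) and `is_buffer` (logical). Structural
#' invariants enforced here: serial positions contiguous from 1 and unique
#' within a list, buffer items neutral, and no word repeated within a list.
#'
#' @param df data.frame with the columns above.
#' @return the validated table, class `stimulus_lists`, sorted by
#'   (list_id, serial_position).
#' @export
stimulus_lists <- function(df) {
  .check_cols(df, LIST_COLS, "lists table")
  df <- as.data.frame(df)[LIST_COLS]
  df$list_id <- as.character(df$list_id)
  df$serial_position <- as.integer(df$serial_position)
  df$word <- normalize_word(df$word)
  df$category <- as.character(df$category)
  df$is_buffer <- as.logical(df$is_buffer)
  .check_values(df$category, CATEGORIES, "lists column 'category'")
  if (anyNA(df$is_buffer)) abort_schema("lists column 'is_buffer' must be 0/1")
  df <- df[order(df$list_id, df$serial_position), , drop = FALSE]
  rownames(df) <- NULL
  for (lid in unique(df$list_id)) {
    sub <- df[df$list_id == lid, , drop = FALSE]
    if (!identical(sort(sub$serial_position), seq_len(nrow(sub)))) {
      abort_schema(sprintf(
        "list '%s': serial positions must be contiguous 1..%d and unique",
        lid, nrow(sub)))
    }
    if (anyDuplicated(sub$word)) {
      abort_duplicate(sprintf("list '%s': word '%s' appears more than once",
                              lid, sub$word[duplicated(sub$word)][1]))
    }
    if (any(sub$is_buffer & sub$category != "neutral")) {
      abort_schema(sprintf("list '%s': buffer items must be neutral", lid))
    }
  }
  class(df) <- c("stimulus_lists", "data.frame")
  df
}

#' Number of non-buffer targets per category in a list table
#'
#' @param lists a `stimulus_lists` table.
#' @return named integer vector over categories (counts for the first list;
#'   an error is raised if lists disagree).
#' @keywords internal
targets_per_category <- function(lists) {
  tg <- lists[!lists$is_buffer, , drop = FALSE]
  tab <- table(tg$list_id, factor(tg$category, levels = CATEGORIES))
  if (nrow(tab) == 0) abort_schema("lists table has no target items")
  if (nrow(unique(as.data.frame.matrix(tab))) > 1) {
    abort_schema("lists differ in per-category target counts")
  }
  stats::setNames(as.integer(tab[1, CATEGORIES]), CATEGORIES)
}

## ---- study dataset ----------------------------------------------------

#' Construct a recall study dataset
#'
#' Bundles a long-format recall-event table with its stimulus lists. The
#' event table has one row per recalled word with columns `participant_id`,
#' `group` (MBCT/control), `timepoint` (T1/T2), `list_id`,
#' `output_position` (1-based within a recall sequence) and `word`. After
#' [score_study()] it additionally carries `classification` and `category`.
#'
#' @param events recall-event data.frame.
#' @param lists stimulus-list data.frame (passed through [stimulus_lists()]).
#' @param lists_per_assessment number of lists each participant recalls at
#'   each timepoint (3 in the reference design); used for recall-percentage
#'   denominators so that lists recalled empty still count.
#' @return object of class `recall_study`: a list with elements `events`,
#'   `lists`, `lists_per_assessment`, `scored`.
#' @export
recall_study <- function(events, lists, lists_per_assessment = 3L) {
  .check_cols(events, EVENT_COLS, "events table")
  lists <- if (inherits(lists, "stimulus_lists")) lists else stimulus_lists(lists)
  keep <- intersect(c(EVENT_COLS, "classification", "category"), names(events))
  events <- as.data.frame(events)[keep]
  events$participant_id <- as.character(events$participant_id)
  events$group <- as.character(events$group)
  events$timepoint <- as.character(events$timepoint)
  events$list_id <- as.character(events$list_id)
  events$output_position <- as.integer(events$output_position)
  events$word <- normalize_word(events$word)
  .check_values(events$group, GROUPS, "events column 'group'")
  .check_values(events$timepoint, TIMEPOINTS, "events column 'timepoint'")

  unknown <- setdiff(unique(events$list_id), unique(lists$list_id))
  if (length(unknown)) {
    abort_integrity(sprintf(
      "events reference list_id(s) absent from the lists table: %s",
      paste(unknown, collapse = ", ")))
  }
  key <- paste(events$participant_id, events$timepoint, events$list_id,
               events$output_position, sep = "\r")
  if (anyDuplicated(key)) {
    d <- events[duplicated(key), , drop = FALSE][1, ]
    abort_duplicate(sprintf(
      "duplicate recall row: participant '%s', %s, list '%s', position %d",
      d$participant_id, d$timepoint, d$list_id, d$output_position))
  }
  grp_per_pid <- tapply(events$group, events$participant_id,
                        function(g) length(unique(g)))
  if (any(grp_per_pid > 1)) {
    abort_integrity(sprintf(
      "participant '%s' carries more than one group label",
      names(grp_per_pid)[grp_per_pid > 1][1]))
  }
  o <- order(events$participant_id, events$timepoint, events$list_id,
             events$output_position)
  events <- events[o, , drop = FALSE]
  ## output positions contiguous from 1 within each sequence
  seq_key <- paste(events$participant_id, events$timepoint, events$list_id,
                   sep = "\r")
  pos_ok <- vapply(split(events$output_position, seq_key),
                   function(p) identical(sort(p), seq_along(p)),
                   logical(1))
  if (length(pos_ok) && any(!pos_ok)) {
    abort_schema(sprintf(
      "recall sequence '%s' has non-contiguous output positions",
      gsub("\r", "/", names(pos_ok)[!pos_ok][1])))
  }
  rownames(events) <- NULL
  structure(
    list(events = events, lists = lists,
         lists_per_assessment = as.integer(lists_per_assessment),
         scored = all(c("classification", "category") %in% names(events))),
    class = "recall_study")
}

#' @export
print.recall_study <- function(x, ...) {
  pp <- participants(x)
  cat(sprintf(
    "recall_study: %d participants (%s), %d recall events, %d lists%s\n",
    nrow(pp),
    paste(sprintf("%d %s", as.integer(table(factor(pp$group, GROUPS))[GROUPS]),
                  GROUPS), collapse = " / "),
    nrow(x$events), length(unique(x$lists$list_id)),
    if (x$scored) ", scored" else ""))
  invisible(x)
}

#' Participant roster of a study
#'
#' @param study a `recall_study`.
#' @return data.frame with columns participant_id, group (one row per
#'   participant, sorted by id).
#' @export
participants <- function(study) {
  ev <- study$events
  pp <- unique(ev[c("participant_id", "group")])
  pp <- pp[order(pp$participant_id), , drop = FALSE]
  rownames(pp) <- NULL
  pp
}

## ---- readers / writers ------------------------------------------------

#' Load a study from events and lists CSV files
#'
#' Both files are comma-separated UTF-8 with a header row. The events file
#' needs columns participant_id, group, timepoint, list_id, output_position,
#' word; the lists file needs list_id, serial_position, word, category,
#' is_buffer (0/1). Words are normalized (lowercased, trimmed, ASCII
#' punctuation stripped) and rows are sorted by output/serial position.
#'
#' @param events_path,lists_path file paths.
#' @param lists_per_assessment see [recall_study()].
#' @return a validated `recall_study`.
#' @export
load_study <- function(events_path, lists_path, lists_per_assessment = 3L) {
  for (p in c(events_path, lists_path)) {
    if (!file.exists(p)) abort_schema(sprintf("file not found: %s", p))
  }
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  ls <- utils::read.csv(lists_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .check_cols(ev, EVENT_COLS, basename(events_path))
  .check_cols(ls, LIST_COLS, basename(lists_path))
  ev$output_position <- as.integer(ev$output_position)
  ls$serial_position <- as.integer(ls$serial_position)
  .check_values(ls$is_buffer, c("0", "1", "TRUE", "FALSE"),
                "lists column 'is_buffer'")
  ls$is_buffer <- ls$is_buffer %in% c("1", "TRUE")
  recall_study(ev, ls, lists_per_assessment = lists_per_assessment)
}

#' Write a study to events and lists CSV files
#'
#' Emits the two CSVs in the schema accepted by [load_study()], with
#' deterministic row order (participant, timepoint, list, position). The
#' round trip `load_study(write_study(x))` reproduces `x` field by field.
#'
#' @param study a `recall_study`.
#' @param events_path,lists_path output paths.
#' @return invisibly, the two paths.
#' @export
write_study <- function(study, events_path, lists_path) {
  stopifnot(inherits(study, "recall_study"))
  ev <- study$events[EVENT_COLS]
  ls <- as.data.frame(study$lists)[LIST_COLS]
  ls$is_buffer <- as.integer(ls$is_buffer)
  for (p in c(events_path, lists_path)) {
    dir <- dirname(p)
    if (!dir.exists(dir)) abort_rdyn(sprintf("cannot write to '%s'", p),
                                     "rdyn_io_error")
  }
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ls, lists_path, row.names = FALSE, quote = FALSE)
  invisible(c(events_path, lists_path))
}

#' Write pooled estimates to CSV
#'
#' @param estimates data.frame of dynamics estimates
#'   (metric, category, group, timepoint, numerator, denominator, value).
#' @param path output path.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write permutation results to JSON
#'
#' @param results a list of `permutation_result` objects.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  out <- lapply(results, function(r) r[!vapply(r, is.null, logical(1))])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
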