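#' Score one raw recall sequence against its stimulus list
#'
#' Classifies each recalled word in output order: the first occurrence of a
#' list target is a `target` (carrying its valence category), the first
#' occurrence of a buffer word is a `buffer`, any later occurrence of an
#' already-recalled list word is a `repetition`, and a word not on the list
#' is an `intrusion`. Matching is exact after [normalize_word()].
#'
#' @param raw_words character vector of recalled words in output order
#'   (possibly empty).
#' @param stim a `stimulus_lists` table restricted to (or containing) the
#'   presented list.
#' @param participant_id,timepoint,list_id identifiers attached to the
#'   returned events.
#' @return data.frame of recall events with columns participant_id,
#'   timepoint, list_id, output_position, word, classification, category
#'   (NA for intrusions/repetitions).
#' @export
#' @examples
#' stim <- stimulus_lists(data.frame(
#'   list_id = "L1", serial_position = 1:2,
#'   word = c("misery", "sunshine"),
#'   category = c("negative", "positive"), is_buffer = FALSE))
#' score_recall_sequence(c("misery", "misery", "table", "sunshine"),
#'                       stim, "P1", "T1", "L1")
score_recall_sequence <- function(raw_words, stim, participant_id,
                                  timepoint, list_id) {
  stim <- if (inherits(stim, "stimulus_lists")) stim else stimulus_lists(stim)
  stim <- stim[stim$list_id == list_id | length(unique(stim$list_id)) == 1, ,
               drop = FALSE]
  words <- normalize_word(raw_words)
  n <- length(words)
  idx <- match(words, stim$word)
  on_list <- !is.na(idx)
  seen <- duplicated(words) & on_list
  classification <- ifelse(!on_list, "intrusion",
                    ifelse(seen, "repetition",
                    ifelse(stim$is_buffer[idx], "buffer", "target")))
  category <- ifelse(on_list & !seen, stim$category[idx], NA_character_)
  data.frame(participant_id = rep(as.character(participant_id), n),
             timepoint = rep(as.character(timepoint), n),
             list_id = rep(as.character(list_id), n),
             output_position = seq_len(n),
             word = words,
             classification = as.character(classification),
             category = as.character(category),
             stringsAsFactors = FALSE)
}

#' Score every recall sequence in a study
#'
#' Vectorized application of the [score_recall_sequence()] rules to all
#' (participant, timepoint, list) sequences. Scoring is idempotent:
#' rescoring a scored study leaves it unchanged.
#'
#' @param study a `recall_study`.
#' @return the study with `classification` and `category` columns added to
#'   its events and `scored = TRUE`.
#' @export
score_study <- function(study) {
  stopifnot(inherits(study, "recall_study"))
  ev <- study$events
  ls <- study$lists
  key <- paste(ev$list_id, ev$word, sep = "\r")
  lkey <- paste(ls$list_id, ls$word, sep = "\r")
  idx <- match(key, lkey)
  on_list <- !is.na(idx)
  ## events are sorted by (participant, timepoint, list, position), so
  ## duplicated() within the sequence-word key marks later occurrences
  seq_word <- paste(ev$participant_id, ev$timepoint, ev$list_id, ev$word,
                    sep = "\r")
  seen <- duplicated(seq_word) & on_list
  ev$classification <- ifelse(!on_list, "intrusion",
                       ifelse(seen, "repetition",
                       ifelse(ls$is_buffer[idx], "buffer", "target")))
  ev$category <- ifelse(on_list & !seen, ls$category[idx], NA_character_)
  study$events <- ev
  study$scored <- TRUE
  study
}

#' Retained valence-category sequence of a scored recall sequence
#'
#' Returns the ordered categories of `target` events only; buffer,
#' intrusion and repetition events are removed (so a transition in the
#' retained sequence "jumps over" excluded events). May be empty.
#'
#' @param events scored event data.frame for one recall sequence (the output
#'   of [score_recall_sequence()], or a subset of scored study events).
#' @return character vector of categories.
#' @export
retained_category_sequence <- function(events) {
  if (!all(c("classification", "category") %in% names(events))) {
    abort_schema("events must be scored (classification/category missing)")
  }
  events <- events[order(events$output_position), , drop = FALSE]
  events$category[events$classification == "target"]
}

## scored target rows of a study, ordered; with per-row first/last flags
## and pooled transition table. Internal workhorse for all dynamics.
.retained <- function(study) {
  if (!study$scored) study <- score_study(study)
  ev <- study$events
  r <- ev[ev$classification == "target", , drop = FALSE]
  o <- order(r$participant_id, r$timepoint, r$list_id, r$output_position)
  r <- r[o, , drop = FALSE]
  key <- paste(r$participant_id, r$timepoint, r$list_id, sep = "\r")
  r$first <- !duplicated(key)
  r$last <- !duplicated(key, fromLast = TRUE)
  r$seq_key <- key
  r
}
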