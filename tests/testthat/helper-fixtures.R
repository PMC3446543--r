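# Fixtures are built in code, deterministically; expensive shared objects
# are memoised for the session.

.fix <- new.env(parent = emptyenv())

fix_norms <- function() {
  if (is.null(.fix$norms)) .fix$norms <- synthetic_word_norms(seed = 8675)
  .fix$norms
}

fix_list_sets <- function() {
  if (is.null(.fix$sets)) {
    .fix$sets <- build_list_sets(fix_norms(), list_spec(), n_lists = 3,
                                 n_sets = 2, seed = 5)
  }
  .fix$sets
}

# a small hand-sized stimulus list: 3 targets per category + 4 buffers
micro_lists <- function(list_id = "L1") {
  words <- c("bufa", "bufb",
             "pos1", "neg1", "neu1", "pos2", "neg2", "neu2", "pos3", "neg3",
             "neu3",
             "bufc", "bufd")
  cats <- c("neutral", "neutral",
            rep(c("positive", "negative", "neutral"), 3),
            "neutral", "neutral")
  stimulus_lists(data.frame(
    list_id = list_id, serial_position = seq_along(words), word = words,
    category = cats,
    is_buffer = c(TRUE, TRUE, rep(FALSE, 9), TRUE, TRUE)))
}

# word spelling that realises a requested retained category sequence
micro_words <- function(cats) {
  counter <- c(positive = 0, negative = 0, neutral = 0)
  vapply(cats, function(cc) {
    counter[cc] <<- counter[cc] + 1
    paste0(substr(cc, 1, 3), counter[cc])
  }, character(1))
}

# build a scored study from a list of sequences; each element gives
# participant, group, timepoint, list and the retained category sequence
micro_study <- function(seqs, lists_per_assessment = 1L) {
  rows <- lapply(seqs, function(s) {
    w <- if (length(s$cats)) micro_words(s$cats) else character()
    if (length(s$extra_words)) w <- c(w, s$extra_words)
    if (!length(w)) return(NULL)
    data.frame(participant_id = s$pid, group = s$group, timepoint = s$tp,
               list_id = s$list %||% "L1", output_position = seq_along(w),
               word = w, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  score_study(recall_study(ev, micro_lists(),
                           lists_per_assessment = lists_per_assessment))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulate a small trial quickly, reusing the memoised list sets
small_trial <- function(n_mbct = 3, n_control = 3, seed = 1,
                        cell_params = null_cell_params(),
                        lists_per_assessment = 3) {
  simulate_trial(trial_design(n_mbct, n_control, lists_per_assessment,
                              cell_params = cell_params, seed = seed),
                 lists = fix_list_sets())
}

# independent brute-force oracles -------------------------------------

bf_no_adjacent <- function(cats) {
  n <- length(cats)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) if (cats[i] == cats[i + 1]) return(FALSE)
  TRUE
}

bf_classify <- function(raw, target_words, buffer_words) {
  out <- character(length(raw))
  recalled <- character()
  for (i in seq_along(raw)) {
    w <- raw[i]
    if (w %in% c(target_words, buffer_words)) {
      if (w %in% recalled) {
        out[i] <- "repetition"
      } else {
        out[i] <- if (w %in% buffer_words) "buffer" else "target"
        recalled <- c(recalled, w)
      }
    } else {
      out[i] <- "intrusion"
    }
  }
  out
}
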