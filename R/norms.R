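#' Generate a synthetic affective word-norms table
#'
#' Produces an ANEW-style norms table of pronounceable-looking pseudo-words
#' with normative valence and arousal drawn (truncated-normally) around the
#' per-category means used for stimulus selection: positive valence
#' 7.5 (SD 0.40) / arousal 5.8 (SD 0.80), negative 2.6 (0.73) / 5.5 (1.37),
#' neutral 5.18 (0.34) / 3.84 (0.48). Word frequency is log-normal
#' (occurrences per million) and word length is the actual character count
#' of the generated token (3-11 letters). This is a synthetic stand-in for
#' proprietary norm databases, intended for simulation and testing; it
#' carries no real lexical content.
#'
#' @param n_per_category number of words generated per valence category
#'   (neutral additionally serves as the buffer pool, so keep it generous).
#' @param seed integer seed; the table is deterministic given the seed.
#' @return data.frame with columns word, valence, arousal, frequency,
#'   length, category_hint (the generating category, informational).
#' @export
#' @examples
#' head(synthetic_word_norms(10, seed = 1))
synthetic_word_norms <- function(n_per_category = 120L, seed = 8675L) {
  set.seed(seed)
  means <- list(
    positive = c(valence = 7.50, arousal = 5.80),
    negative = c(valence = 2.60, arousal = 5.50),
    neutral  = c(valence = 5.18, arousal = 3.84))
  sds <- list(
    positive = c(valence = 0.40, arousal = 0.80),
    negative = c(valence = 0.73, arousal = 1.37),
    neutral  = c(valence = 0.34, arousal = 0.48))
  ## truncation windows keep categories inside their selection windows
  win <- list(
    positive = c(6.8, 9.0), negative = c(1.0, 4.0), neutral = c(4.6, 5.8))

  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n * 4, mean, sd)
    x <- x[x >= lo & x <= hi]
    while (length(x) < n) x <- c(x, rtrunc(n, mean, sd, lo, hi))
    x[seq_len(n)]
  }
  consonants <- strsplit("bcdfgklmnprstvz", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  make_word <- function(len) {
    ch <- character(len)
    ch[seq(1, len, by = 2)] <- sample(consonants, ceiling(len / 2), TRUE)
    if (len > 1) ch[seq(2, len, by = 2)] <- sample(vowels, floor(len / 2), TRUE)
    paste(ch, collapse = "")
  }

  out <- lapply(CATEGORIES, function(cat) {
    lens <- sample(3:11, n_per_category, replace = TRUE,
                   prob = c(2, 4, 6, 6, 5, 4, 3, 2, 1))
    words <- vapply(lens, make_word, character(1))
    data.frame(
      word = words,
      valence = round(rtrunc(n_per_category, means[[cat]]["valence"],
                             sds[[cat]]["valence"], win[[cat]][1],
                             win[[cat]][2]), 2),
      arousal = round(rtrunc(n_per_category, means[[cat]]["arousal"],
                             sds[[cat]]["arousal"], 1, 9), 2),
      frequency = round(exp(stats::rnorm(n_per_category, 2.5, 1.0)), 2),
      length = lens,
      category_hint = cat,
      stringsAsFactors = FALSE)
  })
  norms <- do.call(rbind, out)
  norms <- norms[!duplicated(norms$word), , drop = FALSE]
  norms$word <- normalize_word(norms$word)
  rownames(norms) <- NULL
  validate_word_norms(norms)
}

#' Validate a word-norms table
#'
#' Checks the WordNorm invariants: ratings on the 1-9 scale, nonnegative
#' frequency, positive integer length, unique normalized words.
#'
#' @param norms data.frame with columns word, valence, arousal, frequency,
#'   length.
#' @return the table with normalized words, invisibly classed `word_norms`.
#' @export
validate_word_norms <- function(norms) {
  .check_cols(norms, c("word", "valence", "arousal", "frequency", "length"),
              "norms table")
  norms <- as.data.frame(norms)
  norms$word <- normalize_word(norms$word)
  for (col in c("valence", "arousal")) {
    v <- as.numeric(norms[[col]])
    if (anyNA(v) || any(v < 1 | v > 9)) {
      abort_schema(sprintf("norms column '%s' must lie in [1, 9]", col))
    }
    norms[[col]] <- v
  }
  norms$frequency <- as.numeric(norms$frequency)
  if (anyNA(norms$frequency) || any(norms$frequency < 0)) {
    abort_schema("norms column 'frequency' must be nonnegative")
  }
  norms$length <- as.integer(norms$length)
  if (anyNA(norms$length) || any(norms$length < 1)) {
    abort_schema("norms column 'length' must be a positive integer")
  }
  if (anyDuplicated(norms$word)) {
    abort_duplicate(sprintf("norms word '%s' is duplicated",
                            norms$word[duplicated(norms$word)][1]))
  }
  class(norms) <- c("word_norms", "data.frame")
  norms
}
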