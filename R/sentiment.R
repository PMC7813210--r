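#' Construct a sentiment lexicon
#'
#' A HowNet-style word list assigning each word a signed sentiment value.
#'
#' @param word Unique words.
#' @param value Finite signed sentiment values.
#' @return An object of class `sentiment_lexicon` (a data.frame).
#' @export
sentiment_lexicon <- function(word, value) {
  if (length(word) != length(value)) {
    stop_bad_arg("word", "match the length of `value`")
  }
  if (anyDuplicated(word)) stop_bad_arg("word", "be unique")
  value <- as.numeric(value)
  if (any(!is.finite(value))) stop_bad_arg("value", "be finite")
  structure(data.frame(word = as.character(word), value = value),
            class = c("sentiment_lexicon", "data.frame"))
}

#' Load a sentiment lexicon from TSV
#'
#' UTF-8 tab-separated columns `word`, `value`; malformed rows are reported
#' with their line number.
#'
#' @param path Path to the TSV file.
#' @return A [sentiment_lexicon()].
#' @export
read_sentiment_lexicon <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", colClasses = "character")
  if (!all(c("word", "value") %in% names(raw))) {
    stop(sprintf("%s: expected columns word, value", path), call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value) | !nzchar(raw$word))
  if (length(bad)) {
    stop(sprintf("%s line %d: malformed row", path, bad[1L] + 1L), call. = FALSE)
  }
  dup <- which(duplicated(raw$word))
  if (length(dup)) {
    stop(sprintf("%s line %d: duplicate word '%s'", path, dup[1L] + 1L,
                 raw$word[dup[1L]]), call. = FALSE)
  }
  sentiment_lexicon(raw$word, value)
}

#' Polarity of a sentiment value
#'
#' Sign rule with an optional dead-band: `+1` when `s > epsilon`, `-1` when
#' `s < -epsilon`, `0` otherwise. The default `epsilon = 0` makes the neutral
#' class exactly `s == 0`.
#'
#' @param s Finite numeric sentiment value(s).
#' @param epsilon Non-negative half-width of the neutral dead-band.
#' @return Integer polarity in `{+1, 0, -1}`, vectorised over `s`.
#' @export
polarity <- function(s, epsilon = 0) {
  if (!is.numeric(s) || any(!is.finite(s))) {
    stop_bad_arg("s", "be finite numeric")
  }
  if (!is_scalar_number(epsilon) || epsilon < 0) {
    stop_bad_arg("epsilon", "be a single number >= 0")
  }
  ifelse(s > epsilon, 1L, ifelse(s < -epsilon, -1L, 0L))
}

#' Sentiment value and polarity of a token sequence
#'
#' The sentence sentiment value is the sum of per-word lexicon values over
#' the sequence; out-of-lexicon words contribute 0 (they still count toward
#' the sequence length `k`). Polarity follows [polarity()].
#'
#' @param tokens Character vector of pre-segmented tokens.
#' @param lexicon A [sentiment_lexicon()].
#' @param epsilon Neutral dead-band passed to [polarity()].
#' @return List with `s_x` (signed value), `t_x` (polarity), `k` (token count).
#' @examples
#' lex <- sentiment_lexicon(c("好", "差"), c(1, -1))
#' sentence_sentiment(c("好", "好", "差"), lex)
#' @export
sentence_sentiment <- function(tokens, lexicon, epsilon = 0) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  idx <- match(tokens, lexicon$word)
  s_x <- sum(lexicon$value[idx], na.rm = TRUE)
  list(s_x = s_x, t_x = polarity(s_x, epsilon), k = length(tokens))
}

#' Adjudicate a three-rater panel
#'
#' Protocol: when raters A and B agree, their shared label is final; when
#' they disagree, rater C decides. With binary labels this coincides with the
#' 2-of-3 majority.
#'
#' @param label_a,label_b,label_c Vectors of labels in `{+1, -1}`.
#' @return Integer vector of final labels.
#' @export
adjudicate <- function(label_a, label_b, label_c) {
  labs <- list(label_a, label_b, label_c)
  for (l in labs) {
    if (!all(l %in% c(-1L, 1L))) {
      stop_bad_arg("labels", "all lie in {+1, -1}")
    }
  }
  n <- unique(lengths(labs))
  if (length(n) != 1L) stop_bad_arg("labels", "have equal lengths")
  as.integer(ifelse(label_a == label_b, label_a, label_c))
}

#' Summarise corpus polarity counts and proportions
#'
#' @param labels Non-empty vector of polarities in `{+1, 0, -1}`.
#' @return An object of class `sentiment_summary`: counts `np` (+1), `nn`
#'   (-1), `zn` (0), total `n`, and `pos_pct`/`neg_pct` as percentages rounded
#'   to one decimal (raw fractions kept as `pos_frac`/`neg_frac`).
#' @examples
#' sentiment_summary(c(rep(1, 441), rep(-1, 295), rep(0, 189)))
#' @export
sentiment_summary <- function(labels) {
  if (length(labels) == 0L) {
    stop("degenerate input: empty label list", call. = FALSE)
  }
  if (!all(labels %in% c(-1L, 0L, 1L))) {
    stop_bad_arg("labels", "all lie in {+1, 0, -1}")
  }
  np <- sum(labels == 1L); nn <- sum(labels == -1L); zn <- sum(labels == 0L)
  n <- length(labels)
  structure(
    list(np = np, nn = nn, zn = zn, n = n,
         pos_frac = np / n, neg_frac = nn / n,
         pos_pct = round(100 * np / n, 1), neg_pct = round(100 * nn / n, 1)),
    class = "sentiment_summary"
  )
}

#' @export
print.sentiment_summary <- function(x, ...) {
  cat(sprintf("sentiment summary over %d messages:\n", x$n))
  cat(sprintf("  positive %d (%.1f%%), negative %d (%.1f%%), neutral %d\n",
              x$np, x$pos_pct, x$nn, x$neg_pct, x$zn))
  invisible(x)
}

#' Agreement between lexicon-based and manual polarity labels
#'
#' Builds the 3x3 confusion table over `{+1, 0, -1}` (manual labels are
#' binary, so the manual-neutral column is structurally empty) and reports
#' the overall agreement fraction, the table's trace over its total.
#'
#' @param lexicon_labels,manual_labels Aligned label vectors of equal length.
#' @return An object of class `method_agreement`: `table` (3x3 matrix, rows
#'   = lexicon labels, columns = manual labels) and `agreement` in `[0, 1]`.
#' @export
method_agreement <- function(lexicon_labels, manual_labels) {
  if (length(lexicon_labels) != length(manual_labels)) {
    stop_bad_arg("manual_labels", "have the same length as `lexicon_labels`")
  }
  lv <- c("1", "0", "-1")
  tab <- table(
    lexicon = factor(as.integer(lexicon_labels), levels = c(1L, 0L, -1L)),
    manual = factor(as.integer(manual_labels), levels = c(1L, 0L, -1L))
  )
  tab <- matrix(as.integer(tab), 3L, 3L, dimnames = list(lexicon = lv, manual = lv))
  structure(
    list(table = tab,
         agreement = sum(diag(tab)) / length(lexicon_labels)),
    class = "method_agreement"
  )
}

#' @export
print.method_agreement <- function(x, ...) {
  cat(sprintf("overall agreement: %.3f\n", x$agreement))
  print(x$table)
  invisible(x)
}
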