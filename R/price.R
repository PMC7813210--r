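#' Construct a price lexicon
#'
#' A weighted synonym dictionary for price talk: each entry is a word (or
#' multi-token phrase), a positive weight, and the side it argues for —
#' `expensive` or `cheap`. A word may appear on at most one side.
#'
#' @param word Character vector of words/phrases.
#' @param weight Positive weights.
#' @param side `"expensive"` or `"cheap"` per word.
#' @return An object of class `price_lexicon` (a data.frame).
#' @export
price_lexicon <- function(word, weight, side) {
  if (length(word) != length(weight) || length(word) != length(side)) {
    stop_bad_arg("word", "match the lengths of `weight` and `side`")
  }
  side <- as.character(side)
  bad_side <- which(!side %in% c("expensive", "cheap"))
  if (length(bad_side)) {
    stop(sprintf("invalid side '%s' (entry %d)", side[bad_side[1L]], bad_side[1L]),
         call. = FALSE)
  }
  weight <- as.numeric(weight)
  bad_w <- which(!is.finite(weight) | weight <= 0)
  if (length(bad_w)) {
    stop(sprintf("non-positive or missing weight (entry %d)", bad_w[1L]),
         call. = FALSE)
  }
  dup <- which(duplicated(word))
  if (length(dup)) {
    stop(sprintf("duplicate word '%s' (entry %d); a word may appear on one side only",
                 word[dup[1L]], dup[1L]), call. = FALSE)
  }
  structure(data.frame(word = as.character(word), weight = weight, side = side),
            class = c("price_lexicon", "data.frame"))
}

#' Load a price lexicon from TSV
#'
#' Expects UTF-8 tab-separated columns `word`, `weight`, `side`. Malformed
#' rows are reported with their line number; the loaded lexicon is
#' order-independent.
#'
#' @param path Path to the TSV file.
#' @return A [price_lexicon()].
#' @export
read_price_lexicon <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", colClasses = "character")
  if (!all(c("word", "weight", "side") %in% names(raw))) {
    stop(sprintf("%s: expected columns word, weight, side", path), call. = FALSE)
  }
  weight <- suppressWarnings(as.numeric(raw$weight))
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L  # header occupies line 1
    if (is.na(weight[i]) || !nzchar(raw$word[i])) {
      stop(sprintf("%s line %d: malformed row", path, line), call. = FALSE)
    }
    if (weight[i] <= 0) {
      stop(sprintf("%s line %d: weight must be > 0", path, line), call. = FALSE)
    }
    if (!raw$side[i] %in% c("expensive", "cheap")) {
      stop(sprintf("%s line %d: side must be expensive or cheap", path, line),
           call. = FALSE)
    }
    if (i > 1L && raw$word[i] %in% raw$word[seq_len(i - 1L)]) {
      stop(sprintf("%s line %d: word '%s' already defined", path, line,
                   raw$word[i]), call. = FALSE)
    }
  }
  price_lexicon(raw$word, weight, raw$side)
}

# Greedy longest-first match of lexicon phrases against a token stream.
# A phrase matches a run of consecutive tokens whose concatenation equals it;
# matched tokens are consumed, so overlapping shorter words inside a matched
# phrase are not double-counted.
match_phrases <- function(tokens, words) {
  n <- length(tokens)
  if (n == 0L || length(words) == 0L) return(character(0))
  max_chars <- max(nchar(words))
  hits <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    span <- 0L
    chars <- 0L
    # longest candidate span whose concatenation could still fit a phrase
    while (i + span <= n && chars + nchar(tokens[i + span]) <= max_chars) {
      chars <- chars + nchar(tokens[i + span])
      span <- span + 1L
    }
    for (L in rev(seq_len(max(span, 1L)))) {
      if (i + L - 1L > n) next
      cand <- paste0(tokens[i:(i + L - 1L)], collapse = "")
      if (cand %in% words) {
        hits <- c(hits, cand)
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  hits
}

#' Weighted score of one side of the price lexicon
#'
#' Sum of lexicon weights over every matched occurrence (not type) of a word
#' of the given side in the token sequence. Multi-token phrases are matched
#' greedily longest-first, so a phrase consumes the tokens it spans.
#'
#' @param tokens Character vector of pre-segmented tokens.
#' @param lexicon A [price_lexicon()].
#' @param side `"expensive"` or `"cheap"`.
#' @return Non-negative score; 0 when nothing matches.
#' @export
side_score <- function(tokens, lexicon, side = c("expensive", "cheap")) {
  side <- match.arg(side)
  stopifnot(inherits(lexicon, "price_lexicon"))
  hits <- match_phrases(tokens, lexicon$word)
  if (length(hits) == 0L) return(0)
  idx <- match(hits, lexicon$word)
  sum(lexicon$weight[idx][lexicon$side[idx] == side])
}

#' Price tendency of a token sequence
#'
#' The tendency statistic `s = score_expensive - score_cheap`: positive when
#' the message leans toward calling the price high, negative when it reads
#' the price as acceptable, zero (labelled neutral) otherwise. Antisymmetric
#' under swapping the two sides' word lists.
#'
#' @inheritParams side_score
#' @return An object of class `price_tendency`: `score_expensive`,
#'   `score_cheap`, `s`, `label` in expensive/acceptable/neutral.
#' @examples
#' lex <- price_lexicon(c("贵", "便宜"), c(1, 1),
#'                      c("expensive", "cheap"))
#' price_tendency(c("贵", "贵", "便宜"), lex)
#' @export
price_tendency <- function(tokens, lexicon) {
  e <- side_score(tokens, lexicon, "expensive")
  c_ <- side_score(tokens, lexicon, "cheap")
  s <- e - c_
  label <- if (s > 0) "expensive" else if (s < 0) "acceptable" else "neutral"
  structure(list(score_expensive = e, score_cheap = c_, s = s, label = label),
            class = "price_tendency")
}

#' @export
print.price_tendency <- function(x, ...) {
  cat(sprintf("price tendency s = %g (expensive %g - cheap %g): %s\n",
              x$s, x$score_expensive, x$score_cheap, x$label))
  invisible(x)
}

#' Daily price-tendency series of a message corpus
#'
#' Per-day tendency is the weighted sum of per-message tendencies, with unit
#' weights (`weighting = "none"`, a message-count view) or like counts
#' (`weighting = "likes"`, an endorsement view). Normalisation divides the
#' series by its maximum absolute value, mapping it into `[-1, 1]`.
#'
#' @param messages A data.frame with columns `date` and `tokens` (a list
#'   column of token vectors), plus `likes` when `weighting = "likes"`.
#' @param lexicon A [price_lexicon()].
#' @param weighting `"none"` or `"likes"`.
#' @param normalize Divide by `max(|daily score|)`.
#' @return A data.frame `date`, `raw`, `normalized` (the latter only when
#'   `normalize = TRUE`).
#' @export
corpus_tendency <- function(messages, lexicon,
                            weighting = c("none", "likes"), normalize = TRUE) {
  weighting <- match.arg(weighting)
  if (!all(c("date", "tokens") %in% names(messages))) {
    stop_bad_arg("messages", "have columns `date` and `tokens`")
  }
  if (weighting == "likes") {
    if (is.null(messages$likes) || anyNA(messages$likes)) {
      stop_bad_arg("messages", "carry complete `likes` when weighting = 'likes'")
    }
  }
  s_m <- vapply(messages$tokens, function(tk) price_tendency(tk, lexicon)$s,
                numeric(1))
  w_m <- if (weighting == "likes") as.numeric(messages$likes) else 1
  daily <- stats::aggregate(x = list(raw = s_m * w_m),
                            by = list(date = as.Date(messages$date)), FUN = sum)
  daily <- daily[order(daily$date), , drop = FALSE]
  if (normalize) {
    m <- max(abs(daily$raw))
    daily$normalized <- if (m > 0) daily$raw / m else daily$raw
  }
  rownames(daily) <- NULL
  daily
}
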