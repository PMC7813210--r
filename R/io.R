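#' Read a message table from CSV or JSON Lines
#'
#' The CSV schema stores tokens as a single space-separated field; JSONL
#' stores them as an array per record. Either way the returned table carries
#' a `tokens` list column ready for the scoring functions. Raw-text corpora
#' may instead carry a `text` column plus a caller-supplied `tokenizer`
#' function (tokenization is an injectable adapter, never embedded here).
#'
#' @param path File path ending in `.csv` or `.jsonl`.
#' @param tokenizer Optional function mapping a character vector of texts to
#'   a list of token vectors, applied when the file has `text` but no
#'   `tokens`.
#' @return Data.frame with columns `id`, `date`, `tokens` (list column),
#'   `likes`, `forwards`, `comments`, `topic_id`.
#' @export
read_messages <- function(path, tokenizer = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else if (ext %in% c("jsonl", "ndjson")) {
    lines <- readLines(path, encoding = "UTF-8")
    recs <- lapply(lines[nzchar(lines)], jsonlite::fromJSON)
    raw <- do.call(rbind, lapply(recs, function(r) {
      data.frame(id = r$id, date = r$date,
                 tokens = paste(unlist(r$tokens), collapse = " "),
                 text = r$text %||% NA_character_,
                 likes = r$likes %||% NA, forwards = r$forwards %||% NA,
                 comments = r$comments %||% NA,
                 topic_id = r$topic_id %||% NA_character_)
    }))
  } else {
    stop_bad_arg("path", "end in .csv or .jsonl")
  }
  if (!is.null(raw$tokens) && !is.list(raw$tokens)) {
    raw$tokens <- strsplit(as.character(raw$tokens), " +")
  } else if (is.null(raw$tokens)) {
    if (is.null(raw$text) || is.null(tokenizer)) {
      stop_bad_arg("path", "contain a `tokens` column, or `text` plus a tokenizer")
    }
    raw$tokens <- tokenizer(as.character(raw$text))
  }
  raw$date <- as.Date(raw$date)
  raw
}

#' Write a message table to CSV
#'
#' Inverse of [read_messages()] for the CSV schema; the `tokens` list column
#' is flattened to space-separated fields.
#'
#' @param messages Message data.frame with a `tokens` list column.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_messages <- function(messages, path) {
  out <- messages
  out$tokens <- vapply(out$tokens, paste, character(1), collapse = " ")
  keep <- intersect(c("id", "date", "tokens", "likes", "forwards", "comments",
                      "topic_id"), names(out))
  utils::write.csv(out[, keep, drop = FALSE], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a reading-series CSV
#'
#' Columns `date`, `reads` and optionally `topic_id`; pooled by day via
#' [as_reading_series()].
#'
#' @param path CSV path.
#' @param cumulative Treat `reads` as cumulative and difference it.
#' @return A [reading_series()].
#' @export
read_reading_series <- function(path, cumulative = FALSE) {
  as_reading_series(utils::read.csv(path, stringsAsFactors = FALSE),
                    cumulative = cumulative)
}
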