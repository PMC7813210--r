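VACCINE_TYPES <- c("inactivated", "adenovirus_vector",
                   "attenuated_influenza_vector", "recombinant_protein",
                   "nucleic_acid")

ENGAGEMENT_DIMENSIONS <- c("discussions", "forwards", "comments", "likes")

#' Default keyword map for the five vaccine development routes
#'
#' China's five COVID-19 vaccine development routes, each with a small default
#' list of Chinese mention keywords. The map is configuration: callers may
#' supply their own, subject to keywords being disjoint across types.
#'
#' @return Named list of character vectors, one per vaccine type.
#' @export
default_vaccine_keywords <- function() {
  list(
    inactivated = c("灭活", "灭活疫苗"),
    adenovirus_vector = c("腺病毒", "腺病毒载体"),
    attenuated_influenza_vector = c("减毒", "减毒流感"),
    recombinant_protein = c("重组蛋白", "蛋白亚单位"),
    nucleic_acid = c("核酸", "mRNA", "DNA疫苗")
  )
}

validate_keyword_map <- function(keyword_map) {
  if (!all(VACCINE_TYPES %in% names(keyword_map))) {
    stop_bad_arg("keyword_map", "cover all five vaccine types")
  }
  all_kw <- unlist(keyword_map[VACCINE_TYPES], use.names = FALSE)
  if (anyDuplicated(all_kw)) {
    stop(sprintf("keyword '%s' appears under more than one vaccine type",
                 all_kw[duplicated(all_kw)][1L]), call. = FALSE)
  }
  invisible(keyword_map)
}

#' Classify a message's vaccine type from its tokens
#'
#' Returns the unique vaccine type whose keywords occur among the tokens;
#' `NA` when no keyword matches, and `NA` (with an optional log message) when
#' keywords of more than one type are present, since the mention is ambiguous.
#'
#' @param tokens Character vector of pre-segmented tokens.
#' @param keyword_map Named list of keyword vectors per type; defaults to
#'   [default_vaccine_keywords()].
#' @param quiet Suppress the log message on ambiguous matches.
#' @return A vaccine type string, or `NA_character_`.
#' @export
classify_vaccine_type <- function(tokens, keyword_map = default_vaccine_keywords(),
                                  quiet = FALSE) {
  validate_keyword_map(keyword_map)
  hit <- vapply(keyword_map[VACCINE_TYPES],
                function(kw) any(kw %in% tokens), logical(1))
  types <- VACCINE_TYPES[hit]
  if (length(types) == 1L) return(types)
  if (length(types) > 1L && !quiet) {
    message(sprintf("ambiguous vaccine mention (%s); classified as none",
                    paste(types, collapse = ", ")))
  }
  NA_character_
}

#' Aggregate per-type engagement records from a message corpus
#'
#' Classifies each message by vaccine type and aggregates the four
#' engagement dimensions: `discussions` counts classified messages;
#' `forwards`, `comments`, `likes` sum the message metadata. Messages
#' classified to none are excluded.
#'
#' @param messages Data.frame with a `tokens` list column and numeric
#'   `forwards`, `comments`, `likes` columns.
#' @param keyword_map Keyword configuration per vaccine type.
#' @return Data.frame with one row per vaccine type (all five always
#'   present) and columns for the four dimensions.
#' @export
engagement_records <- function(messages, keyword_map = default_vaccine_keywords()) {
  validate_keyword_map(keyword_map)
  need <- c("tokens", "forwards", "comments", "likes")
  if (!all(need %in% names(messages))) {
    stop_bad_arg("messages", "have columns tokens, forwards, comments, likes")
  }
  type <- vapply(messages$tokens,
                 function(tk) classify_vaccine_type(tk, keyword_map, quiet = TRUE),
                 character(1))
  out <- data.frame(vaccine_type = VACCINE_TYPES,
                    discussions = 0, forwards = 0, comments = 0, likes = 0)
  keep <- !is.na(type)
  if (any(keep)) {
    f <- factor(type[keep], levels = VACCINE_TYPES)
    out$discussions <- as.numeric(table(f))
    out$forwards <- as.numeric(tapply(as.numeric(messages$forwards[keep]), f,
                                      sum, default = 0))
    out$comments <- as.numeric(tapply(as.numeric(messages$comments[keep]), f,
                                      sum, default = 0))
    out$likes <- as.numeric(tapply(as.numeric(messages$likes[keep]), f,
                                   sum, default = 0))
  }
  out
}

#' Attention shares per vaccine type and engagement dimension
#'
#' For each dimension, a type's share is its count over the dimension's total
#' across the five types. Shares sum to 1 exactly per dimension (pre-
#' rounding); display percentages are rounded to the nearest integer. A
#' dimension whose total is zero has undefined shares and is flagged.
#'
#' @param records Data.frame as returned by [engagement_records()]:
#'   `vaccine_type` plus numeric columns `discussions`, `forwards`,
#'   `comments`, `likes` (any subset of dimensions is accepted).
#' @return An object of class `attention_profile`: a long data.frame with
#'   columns `vaccine_type`, `dimension`, `count`, `share`, `pct`, with the
#'   flagged zero-total dimensions in attribute `undefined_dimensions`.
#' @examples
#' rec <- data.frame(
#'   vaccine_type = c("inactivated", "adenovirus_vector",
#'                    "attenuated_influenza_vector", "recombinant_protein",
#'                    "nucleic_acid"),
#'   discussions = c(700, 200, 87, 80, 50))
#' attention_shares(rec)
#' @export
attention_shares <- function(records) {
  if (!"vaccine_type" %in% names(records)) {
    stop_bad_arg("records", "have a `vaccine_type` column")
  }
  if (!all(records$vaccine_type %in% VACCINE_TYPES)) {
    stop_bad_arg("records", "use the closed five-type vaccine set")
  }
  if (anyDuplicated(records$vaccine_type)) {
    stop_bad_arg("records", "have one row per vaccine type")
  }
  dims <- intersect(ENGAGEMENT_DIMENSIONS, names(records))
  if (length(dims) == 0L) {
    stop_bad_arg("records", "contain at least one engagement dimension column")
  }
  rows <- list()
  undefined <- character(0)
  for (d in dims) {
    cnt <- as.numeric(records[[d]])
    if (any(!is.finite(cnt)) || any(cnt < 0)) {
      stop_bad_arg("records", "have finite non-negative counts")
    }
    tot <- sum(cnt)
    share <- if (tot > 0) cnt / tot else rep(NA_real_, length(cnt))
    if (tot == 0) undefined <- c(undefined, d)
    rows[[d]] <- data.frame(vaccine_type = records$vaccine_type, dimension = d,
                            count = cnt, share = share,
                            pct = round(100 * share))
  }
  if (length(undefined)) {
    warning(sprintf("zero total in dimension(s): %s; shares undefined",
                    paste(undefined, collapse = ", ")), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("attention_profile", "data.frame"),
            undefined_dimensions = undefined)
}

#' @export
print.attention_profile <- function(x, ...) {
  cat("attention profile (share of each dimension's total):\n")
  for (d in unique(x$dimension)) {
    sub <- x[x$dimension == d, , drop = FALSE]
    cat(sprintf("  %s: %s\n", d,
                paste(sprintf("%s %s%%", sub$vaccine_type,
                              ifelse(is.na(sub$pct), "NA", sub$pct)),
                      collapse = ", ")))
  }
  invisible(x)
}
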