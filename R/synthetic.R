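# Neutral filler vocabulary for synthetic token streams. Chosen so no filler
# (or concatenation of adjacent fillers) collides with the packaged lexicons
# or vaccine keywords.
FILLER_TOKENS <- c("今天", "消息", "大家", "觉得", "真的", "这个",
                   "已经", "可以", "看到", "希望")

#' Generate a synthetic daily reading series
#'
#' Simulates the SRS/I model and emits its daily new-reader counts, either
#' deterministically or with Poisson count noise around the deterministic
#' incidence, together with the generating ground truth.
#'
#' @param params An [srsi_params()].
#' @param init An [srsi_state()].
#' @param t_grid Daily time grid (days); the series has `length(t_grid) - 1`
#'   counts, one per interval.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed (mandatory).
#' @param origin Calendar date mapped to `t_grid[1]`.
#' @return List with `series` (a [reading_series()]) and `truth` (generating
#'   `params`, `init`, and the reproduction ratio `r0`).
#' @export
gen_reading_series <- function(params, init, t_grid,
                               noise = c("none", "poisson"), seed,
                               origin = as.Date("2020-01-25")) {
  noise <- match.arg(noise)
  if (missing(seed)) stop_bad_arg("seed", "be supplied")
  inc <- srsi_daily_incidence(params, init, t_grid)
  reads <- switch(noise,
    none = inc,
    poisson = with_seed(seed, stats::rpois(length(inc), pmax(inc, 0)))
  )
  dates <- origin + utils::head(t_grid, -1L) - t_grid[1L]
  list(
    series = reading_series(dates, reads),
    truth = list(params = params, init = init,
                 r0 = reproduction_ratio(params, init$S))
  )
}

#' Specification of a synthetic opinion corpus
#'
#' Bundles the mixture proportions and engagement model from which
#' [gen_opinion_corpus()] draws messages with known ground truth.
#'
#' @param n_messages Number of messages.
#' @param date_range Length-2 vector of first and last calendar dates.
#' @param price_mix Probability triple (expensive, cheap, neutral); sums to 1.
#' @param sentiment_mix Probability triple (+1, 0, -1); sums to 1.
#' @param irony_rate Probability that a message's sentiment-bearing words are
#'   sign-flipped relative to its ground-truth label (surface/label mismatch,
#'   the failure mode of lexicon scoring on ironic text).
#' @param vaccine_type_probs Probability 5-vector over the vaccine types, in
#'   the order of [default_vaccine_keywords()]; sums to 1.
#' @param likes_mean,likes_dispersion Mean and dispersion (`size`) of the
#'   negative-binomial like-count model; forwards and comments use scaled
#'   means under the same dispersion.
#' @param seed Integer seed (mandatory).
#' @return An object of class `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_messages,
                                  date_range = as.Date(c("2020-09-01", "2020-09-30")),
                                  price_mix = c(expensive = 0.3, cheap = 0.5, neutral = 0.2),
                                  sentiment_mix = c(pos = 0.477, neu = 0.204, neg = 0.319),
                                  irony_rate = 0,
                                  vaccine_type_probs = c(0.5, 0.2, 0.1, 0.1, 0.1),
                                  likes_mean = 5, likes_dispersion = 0.8,
                                  seed) {
  if (missing(seed)) stop_bad_arg("seed", "be supplied")
  if (!is_scalar_number(n_messages) || n_messages < 1) {
    stop_bad_arg("n_messages", "be a positive count")
  }
  check_simplex <- function(x, name, k) {
    if (length(x) != k || any(x < 0) || abs(sum(x) - 1) > 1e-8) {
      stop_bad_arg(name, sprintf("be %d non-negative probabilities summing to 1", k))
    }
  }
  check_simplex(price_mix, "price_mix", 3L)
  check_simplex(sentiment_mix, "sentiment_mix", 3L)
  check_simplex(vaccine_type_probs, "vaccine_type_probs", 5L)
  if (!is_scalar_number(irony_rate) || irony_rate < 0 || irony_rate > 1) {
    stop_bad_arg("irony_rate", "lie in [0, 1]")
  }
  if (likes_mean < 0 || likes_dispersion <= 0) {
    stop_bad_arg("likes_mean", "be >= 0 with dispersion > 0")
  }
  structure(
    list(n_messages = as.integer(n_messages), date_range = as.Date(date_range),
         price_mix = unname(price_mix), sentiment_mix = unname(sentiment_mix),
         irony_rate = irony_rate, vaccine_type_probs = unname(vaccine_type_probs),
         likes_mean = likes_mean, likes_dispersion = likes_dispersion,
         seed = as.integer(seed)),
    class = "synthetic_corpus_spec"
  )
}

#' Generate a synthetic opinion corpus with ground truth
#'
#' Draws messages whose token streams realise planted price, sentiment and
#' vaccine-type labels: an "expensive" message contains 1-3 expensive-side
#' lexicon words (and none of the other side), a positive message contains
#' 1-3 positive-value words, and so on, mixed with neutral filler tokens.
#' With `irony_rate = 0` every planted label is exactly recoverable by the
#' scoring modules. With probability `irony_rate` a non-neutral message's
#' sentiment words are drawn from the opposite sign while its ground-truth
#' label is kept, emulating ironic phrasing.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @param price_lexicon A [price_lexicon()] with words on both sides.
#' @param sentiment_lexicon A [sentiment_lexicon()] with both signs present.
#' @param keyword_map Vaccine keyword configuration.
#' @return List with `messages` (id, date, tokens list-column, likes,
#'   forwards, comments, topic_id) and `truth` (id, price_label,
#'   sentiment_label, vaccine_type, ironic).
#' @export
gen_opinion_corpus <- function(spec, price_lexicon, sentiment_lexicon,
                               keyword_map = default_vaccine_keywords()) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"),
            inherits(price_lexicon, "price_lexicon"),
            inherits(sentiment_lexicon, "sentiment_lexicon"))
  validate_keyword_map(keyword_map)
  exp_words <- price_lexicon$word[price_lexicon$side == "expensive"]
  cheap_words <- price_lexicon$word[price_lexicon$side == "cheap"]
  pos_words <- sentiment_lexicon$word[sentiment_lexicon$value > 0]
  neg_words <- sentiment_lexicon$word[sentiment_lexicon$value < 0]
  if (spec$price_mix[1L] > 0 && length(exp_words) == 0L ||
      spec$price_mix[2L] > 0 && length(cheap_words) == 0L) {
    stop("price lexicon lacks a side required by `price_mix`", call. = FALSE)
  }
  if ((spec$sentiment_mix[1L] > 0 || spec$irony_rate > 0) && length(pos_words) == 0L ||
      (spec$sentiment_mix[3L] > 0 || spec$irony_rate > 0) && length(neg_words) == 0L) {
    stop("sentiment lexicon lacks a sign required by the spec", call. = FALSE)
  }

  n <- spec$n_messages
  with_seed(spec$seed, {
    price_lab <- sample(c("expensive", "cheap", "neutral"), n, replace = TRUE,
                        prob = spec$price_mix)
    sent_lab <- sample(c(1L, 0L, -1L), n, replace = TRUE,
                       prob = spec$sentiment_mix)
    vax <- sample(VACCINE_TYPES, n, replace = TRUE,
                  prob = spec$vaccine_type_probs)
    ironic <- stats::runif(n) < spec$irony_rate & sent_lab != 0L
    dates <- spec$date_range[1L] +
      sample.int(as.integer(diff(spec$date_range)) + 1L, n, replace = TRUE) - 1L
    likes <- stats::rnbinom(n, size = spec$likes_dispersion, mu = spec$likes_mean)
    forwards <- stats::rnbinom(n, size = spec$likes_dispersion,
                               mu = spec$likes_mean / 2)
    comments <- stats::rnbinom(n, size = spec$likes_dispersion,
                               mu = spec$likes_mean / 1.5)

    tokens <- vector("list", n)
    for (i in seq_len(n)) {
      tk <- sample(FILLER_TOKENS, sample.int(6L, 1L) + 2L, replace = TRUE)
      if (price_lab[i] == "expensive") {
        tk <- c(tk, sample(exp_words, sample.int(3L, 1L), replace = TRUE))
      } else if (price_lab[i] == "cheap") {
        tk <- c(tk, sample(cheap_words, sample.int(3L, 1L), replace = TRUE))
      }
      surface <- if (ironic[i]) -sent_lab[i] else sent_lab[i]
      if (surface == 1L) {
        tk <- c(tk, sample(pos_words, sample.int(3L, 1L), replace = TRUE))
      } else if (surface == -1L) {
        tk <- c(tk, sample(neg_words, sample.int(3L, 1L), replace = TRUE))
      }
      kw <- keyword_map[[vax[i]]]
      tk <- c(tk, kw[sample.int(length(kw), 1L)])
      tokens[[i]] <- sample(tk)
    }
    messages <- data.frame(id = seq_len(n), date = dates, likes = likes,
                           forwards = forwards, comments = comments,
                           topic_id = "synthetic")
    messages$tokens <- tokens
    truth <- data.frame(id = seq_len(n), price_label = price_lab,
                        sentiment_label = sent_lab, vaccine_type = vax,
                        ironic = ironic)
    list(messages = messages, truth = truth)
  })
}

#' Generate synthetic three-rater label panels
#'
#' Each rater independently flips the ground-truth binary label with its own
#' error probability, yielding panels for the A/B/C adjudication protocol.
#' Error rates must stay below 0.5 so majority adjudication improves on any
#' single rater.
#'
#' @param truth Vector of true labels in `{+1, -1}`.
#' @param err_a,err_b,err_c Per-rater flip probabilities in `[0, 0.5)`.
#' @param seed Integer seed (mandatory).
#' @return Data.frame with columns `truth`, `label_a`, `label_b`, `label_c`.
#' @export
gen_rater_panel <- function(truth, err_a, err_b, err_c, seed) {
  if (missing(seed)) stop_bad_arg("seed", "be supplied")
  if (!all(truth %in% c(-1L, 1L))) stop_bad_arg("truth", "all lie in {+1, -1}")
  for (e in c(err_a, err_b, err_c)) {
    if (!is_scalar_number(e) || e < 0 || e >= 0.5) {
      stop_bad_arg("error rates", "lie in [0, 0.5)")
    }
  }
  n <- length(truth)
  with_seed(seed, {
    flip <- function(err) {
      as.integer(ifelse(stats::runif(n) < err, -truth, truth))
    }
    data.frame(truth = as.integer(truth), label_a = flip(err_a),
               label_b = flip(err_b), label_c = flip(err_c))
  })
}
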