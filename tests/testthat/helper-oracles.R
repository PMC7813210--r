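`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent fixed-step Euler integration of the SRS/I system, used as a
# brute-force oracle against the package's adaptive solver. Deliberately
# written from the flow definitions, not from the package's rhs code.
euler_srsi <- function(lam, alpha, p, S0, R0, I0, t_max, h = 1e-3,
                       report_at = 0:t_max) {
  S <- S0; R <- R0; I <- I0
  t <- 0
  out <- matrix(NA_real_, nrow = length(report_at), ncol = 4,
                dimnames = list(NULL, c("t", "S", "R", "I")))
  k <- 1L
  repeat {
    if (k <= length(report_at) && t >= report_at[k] - h / 2) {
      out[k, ] <- c(report_at[k], S, R, I)
      k <- k + 1L
    }
    if (t >= t_max) break
    new_readers <- lam * S * R
    inact <- alpha * R
    S <- S + h * (-new_readers + p * inact)
    R <- R + h * (new_readers - inact)
    I <- I + h * ((1 - p) * inact)
    t <- t + h
  }
  as.data.frame(out)
}

# Two-compartment SIS oracle (no immune class): dS = -lam*S*R + alpha*R,
# dR = lam*S*R - alpha*R. The p = 1 limit of SRS/I must match it.
euler_sis <- function(lam, alpha, S0, R0, t_max, h = 1e-3, report_at = 0:t_max) {
  euler_srsi(lam, alpha, p = 1, S0 = S0, R0 = R0, I0 = 0,
             t_max = t_max, h = h, report_at = report_at)
}

fixture_price_lexicon <- function() {
  read_price_lexicon(system.file("extdata", "price_lexicon_synthetic.tsv",
                                 package = "opiniondyn"))
}

fixture_sentiment_lexicon <- function() {
  read_sentiment_lexicon(system.file("extdata", "sentiment_lexicon_synthetic.tsv",
                                     package = "opiniondyn"))
}

# Random token sequences over a vocabulary, for property-style loops.
random_sentences <- function(n, vocab, min_len = 0L, max_len = 12L) {
  lapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1L)
    if (len == 0L) character(0) else sample(vocab, len, replace = TRUE)
  })
}
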