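tiny_lex <- function() {
  price_lexicon(c("贵", "太贵", "便宜"), c(1, 2, 1),
                c("expensive", "expensive", "cheap"))
}

test_that("lexicon loading validates weights, sides and duplicates", {
  lex <- fixture_price_lexicon()
  expect_s3_class(lex, "price_lexicon")
  expect_equal(nrow(lex), 12)
  expect_setequal(unique(lex$side), c("expensive", "cheap"))

  write_lex <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("word\tweight\tside", lines), f, useBytes = TRUE)
    f
  }
  expect_error(read_price_lexicon(write_lex("x\t0\texpensive")), "line 2")
  expect_error(read_price_lexicon(write_lex(c("x\t1\texpensive", "x\t1\tcheap"))),
               "line 3")
  expect_error(read_price_lexicon(write_lex("x\tabc\texpensive")), "malformed")
  expect_error(read_price_lexicon(write_lex("x\t1\tpricey")), "side")
  # load is order-independent
  a <- read_price_lexicon(write_lex(c("a\t1\texpensive", "b\t2\tcheap")))
  b <- read_price_lexicon(write_lex(c("b\t2\tcheap", "a\t1\texpensive")))
  expect_equal(side_score(c("a", "b"), a, "cheap"),
               side_score(c("a", "b"), b, "cheap"))
})

test_that("side scores sum weights over occurrences with greedy phrase matching", {
  lex <- tiny_lex()
  expect_equal(side_score(c("太贵", "贵"), lex, "expensive"), 3)
  expect_equal(side_score(c("无关", "词语"), lex, "expensive"), 0)
  expect_equal(side_score(character(0), lex, "expensive"), 0)
  # occurrences, not types
  expect_equal(side_score(c("贵", "贵"), lex, "expensive"), 2)
  # the two-token run 太+贵 matches the longer phrase, not the inner word
  expect_equal(side_score(c("太", "贵"), lex, "expensive"), 2)
  # brute-force oracle on single-token lexicons: per-token lookup and sum
  set.seed(7)
  single <- price_lexicon(c("贵", "便宜", "昂贵"), c(1.5, 1.2, 2),
                          c("expensive", "cheap", "expensive"))
  vocab <- c(single$word, "疫苗", "今天", "大家")
  for (tokens in random_sentences(200, vocab)) {
    oracle <- sum(vapply(tokens, function(tk) {
      i <- which(single$word == tk & single$side == "expensive")
      if (length(i)) single$weight[i] else 0
    }, numeric(1)))
    expect_equal(side_score(tokens, single, "expensive"), oracle)
  }
})

test_that("price tendency is the score difference with a sign-consistent label", {
  lex <- tiny_lex()
  res <- price_tendency(c("太贵", "贵", "便宜"), lex)
  expect_equal(res$score_expensive, 3)
  expect_equal(res$score_cheap, 1)
  expect_equal(res$s, 2)
  expect_equal(res$label, "expensive")
  expect_equal(price_tendency(character(0), lex)$label, "neutral")
  expect_equal(price_tendency(c("便宜"), lex)$label, "acceptable")
})

test_that("tendency is antisymmetric under side swap and additive over concatenation", {
  lex <- fixture_price_lexicon()
  swapped <- price_lexicon(lex$word, lex$weight,
                           ifelse(lex$side == "expensive", "cheap", "expensive"))
  set.seed(11)
  vocab <- c(lex$word, "疫苗", "今天", "大家", "觉得")
  sentences <- random_sentences(60, vocab)
  for (tokens in sentences) {
    expect_equal(price_tendency(tokens, swapped)$s,
                 -price_tendency(tokens, lex)$s)
  }
  for (i in seq(1, 59, by = 2)) {
    a <- sentences[[i]]; b <- sentences[[i + 1]]
    expect_equal(price_tendency(c(a, b), lex)$s,
                 price_tendency(a, lex)$s + price_tendency(b, lex)$s)
  }
})

test_that("corpus tendency aggregates per day, weights by likes, and normalizes", {
  lex <- tiny_lex()
  msgs <- data.frame(date = as.Date("2020-09-01") + c(0, 0, 1, 1),
                     likes = c(2, 0, 5, 1))
  msgs$tokens <- list(c("贵"), c("太贵"), c("便宜"), c("便宜", "便宜"))

  out <- corpus_tendency(msgs, lex, weighting = "none")
  expect_equal(out$raw, c(3, -3))       # day1: 1+2; day2: -1-2
  expect_equal(out$normalized, c(1, -1))

  # likes weighting: a zero-like message contributes nothing
  outl <- corpus_tendency(msgs, lex, weighting = "likes")
  expect_equal(outl$raw, c(2 * 1 + 0 * 2, 5 * -1 + 1 * -2))

  # purely expensive corpus: normalized series is positive throughout, with
  # the peak day at exactly +1 (normalization divides by max |daily score|)
  pure <- data.frame(date = as.Date("2020-09-01") + 0:2, likes = 1)
  pure$tokens <- list(c("贵"), c("太贵", "贵"), c("贵"))
  norm <- corpus_tendency(pure, lex)$normalized
  expect_true(all(norm > 0))
  expect_equal(max(norm), 1)
  # equal-score days normalize to +1 everywhere
  flat <- data.frame(date = as.Date("2020-09-01") + 0:2, likes = 1)
  flat$tokens <- list(c("贵"), c("贵"), c("贵"))
  expect_equal(corpus_tendency(flat, lex)$normalized, c(1, 1, 1))

  # mirror-image corpus cancels to zero every day
  mirror <- data.frame(date = as.Date("2020-09-01") + c(0, 0), likes = 1)
  mirror$tokens <- list(c("贵"), c("便宜"))
  expect_equal(corpus_tendency(mirror, lex)$raw, 0)

  msgs_na <- msgs; msgs_na$likes <- NA
  expect_error(corpus_tendency(msgs_na, lex, weighting = "likes"), "likes")
})

test_that("planted daily majorities are recovered in sign at a 60/40 split", {
  lex <- fixture_price_lexicon()
  days <- as.Date("2020-09-01") + 0:9
  majority <- rep(c("expensive", "cheap"), 5)
  # unit-weight words on each side, so a 6:4 message split gives s = +/-2
  rows <- list()
  for (d in seq_along(days)) {
    word_of <- c(expensive = "贵", cheap = "便宜")
    sides <- c(rep(majority[d], 6), rep(setdiff(names(word_of), majority[d]), 4))
    for (s in sides) {
      rows[[length(rows) + 1]] <- list(date = days[d],
                                       tokens = c("疫苗", word_of[[s]]))
    }
  }
  msgs <- data.frame(date = as.Date(vapply(rows, function(r) as.character(r$date), "")))
  msgs$tokens <- lapply(rows, `[[`, "tokens")
  out <- corpus_tendency(msgs, lex, weighting = "none")
  expect_equal(sign(out$normalized),
               ifelse(majority[order(days)] == "expensive", 1, -1))
})
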