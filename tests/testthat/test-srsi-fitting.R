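make_series <- function(n_days, start = as.Date("2020-01-25"), reads = NULL) {
  reading_series(start + 0:(n_days - 1), reads %||% rep(1, n_days))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("stage segmentation partitions days and preserves order", {
  s <- make_series(10, reads = 1:10)
  stg <- stage_definitions(c("a", "b"),
                           start = as.Date(c("2020-01-25", "2020-01-29")),
                           end = as.Date(c("2020-01-28", "2020-02-03")))
  parts <- segment_stages(s, stg)
  expect_named(parts, c("a", "b"))
  expect_equal(nrow(parts$a), 4)
  expect_equal(nrow(parts$b), 6)
  expect_equal(parts$b$reads, 5:10)

  # one stage covering everything is the identity
  all_stage <- stage_definitions("all", as.Date("2020-01-25"), as.Date("2020-02-03"))
  expect_equal(segment_stages(s, all_stage)$all$reads, s$reads)

  # a stage covering no days warns and yields an empty series
  empty_stage <- stage_definitions("none", as.Date("2021-01-01"), as.Date("2021-01-05"))
  expect_warning(parts <- segment_stages(s, empty_stage), "no data")
  expect_equal(nrow(parts$none), 0)

  # overlapping stages are rejected at definition time
  expect_error(
    stage_definitions(c("a", "b"),
                      start = as.Date(c("2020-01-01", "2020-01-05")),
                      end = as.Date(c("2020-01-10", "2020-01-20"))),
    "overlap")
})

test_that("reading series validate their invariants and pool cumulative input", {
  expect_error(reading_series(as.Date(c("2020-01-02", "2020-01-01")), c(1, 2)),
               "increasing")
  expect_error(reading_series(as.Date(c("2020-01-01", "2020-01-02")), c(1, -2)),
               ">= 0")
  # cumulative reading quantity is differenced into daily new reads
  cum <- data.frame(date = as.Date("2020-01-01") + 0:4,
                    reads = c(10, 30, 60, 60, 100))
  s <- as_reading_series(cum, cumulative = TRUE)
  expect_equal(s$reads, c(10, 20, 30, 0, 40))
  # same-day rows across topics are pooled
  two_topics <- data.frame(date = rep(as.Date("2020-01-01") + 0:1, 2),
                           reads = c(1, 2, 10, 20))
  expect_equal(as_reading_series(two_topics)$reads, c(11, 22))
})

test_that("noise-free series are recovered to high relative accuracy", {
  N <- 1e5
  pars <- srsi_params(lam = 3e-5, alpha = 0.4, p = 0.3, N = N)
  init <- srsi_state(S = N - 10, R = 10, I = 0)
  gen <- gen_reading_series(pars, init, 0:60, noise = "none", seed = 1)
  r0_true <- reproduction_ratio(pars, N - 10)
  fit <- fit_srsi(gen$series, N = N, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$r0_hat - r0_true) / r0_true, 1e-3)
  expect_equal(fit$r0_hat, fit$params$lam * fit$S0_hat / fit$params$alpha)
})

test_that("degenerate and undersized inputs are rejected", {
  zeros <- make_series(20, reads = rep(0, 20))
  expect_error(fit_srsi(zeros, N = 1e5), "degenerate")
  expect_error(fit_srsi(make_series(4), N = 1e5), "at least 5")
})

test_that("fitting is deterministic given data and seed, and never worse than the guess", {
  N <- 1e5
  pars <- srsi_params(lam = 2.5e-5, alpha = 1, p = 0.3, N = N)
  init <- srsi_state(S = N - 10, R = 10, I = 0)
  gen <- gen_reading_series(pars, init, 0:40, noise = "poisson", seed = 5)
  f1 <- fit_srsi(gen$series, N = N, seed = 9)
  f2 <- fit_srsi(gen$series, N = N, seed = 9)
  expect_identical(f1$r0_hat, f2$r0_hat)
  expect_identical(f1$sse, f2$sse)

  guess <- srsi_params(lam = 1e-5, alpha = 0.5, p = 0.5, N = N)
  f3 <- fit_srsi(gen$series, N = N, init_guess = guess, seed = 9)
  expect_lte(f3$sse, f3$sse_init)
})

test_that("per-stage fitting recovers the reference ordering and isolates failures", {
  N <- 1e5
  alpha <- 1
  start <- as.Date("2020-01-25")
  r0s <- c(1.14, 2.83, 3.07)
  dates <- c(); reads <- c()
  for (j in seq_along(r0s)) {
    lam <- r0s[j] * alpha / (N - 10)
    pars <- srsi_params(lam = lam, alpha = alpha, p = 0.3, N = N)
    gen <- gen_reading_series(pars, srsi_state(N - 10, 10, 0), 0:60,
                              noise = "none", seed = j,
                              origin = start + (j - 1) * 60)
    dates <- c(dates, gen$series$date)
    reads <- c(reads, gen$series$reads)
  }
  series <- reading_series(as.Date(dates, origin = "1970-01-01"), reads)
  stages <- stage_definitions(c("ferment", "evolution", "transmission"),
                              start = start + c(0, 60, 120),
                              end = start + c(59, 119, 179))
  fits <- stage_reproduction_ratios(series, stages, N = N, seed = 2)
  expect_named(fits, c("ferment", "evolution", "transmission"))
  r0_hat <- vapply(fits, `[[`, numeric(1), "r0_hat")
  expect_true(r0_hat[1] < r0_hat[2] && r0_hat[2] < r0_hat[3])
  # the slow ferment stage sits on a flat (lam, alpha) ridge, so allow a
  # few percent even without noise
  expect_equal(unname(r0_hat), r0s, tolerance = 0.05)

  # a stage with no data is flagged, not fatal
  stages_bad <- stage_definitions(c("ok", "empty"),
                                  start = c(start, start + 400),
                                  end = c(start + 59, start + 420))
  suppressWarnings(fits_bad <- stage_reproduction_ratios(series, stages_bad,
                                                         N = N, seed = 2))
  expect_true(fits_bad$ok$converged)
  expect_false(fits_bad$empty$converged)
  expect_true(is.na(fits_bad$empty$r0_hat))
})

test_that("default stage boundaries span the three 2020 periods", {
  stg <- default_stages()
  expect_equal(stg$name, c("ferment", "evolution", "transmission"))
  expect_equal(stg$start, as.Date(c("2020-01-25", "2020-07-01", "2020-08-01")))
  expect_equal(stg$end, as.Date(c("2020-06-30", "2020-07-31", "2020-10-10")))
})
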