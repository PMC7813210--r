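#' Construct a reading series
#'
#' A dated series of daily new-reading counts for a topic cluster, the unit of
#' data the stage-fitting routines consume.
#'
#' @param dates Vector of `Date`s, strictly increasing.
#' @param reads Non-negative new-reading counts per day.
#' @param topic_id Optional grouping labels (recycled to the series length).
#' @return An object of class `reading_series` (a data.frame).
#' @export
reading_series <- function(dates, reads, topic_id = NULL) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop_bad_arg("dates", "be parseable as dates")
  if (length(dates) != length(reads)) {
    stop_bad_arg("reads", "have the same length as `dates`")
  }
  if (length(dates) > 1L && any(diff(as.numeric(dates)) <= 0)) {
    stop_bad_arg("dates", "be strictly increasing")
  }
  if (!is.numeric(reads) || any(!is.finite(reads)) || any(reads < 0)) {
    stop_bad_arg("reads", "be finite and >= 0")
  }
  out <- data.frame(date = dates, reads = as.numeric(reads))
  if (!is.null(topic_id)) out$topic_id <- rep_len(topic_id, nrow(out))
  structure(out, class = c("reading_series", "data.frame"))
}

#' Coerce a raw table to a reading series
#'
#' Pools counts by calendar day (summing across topics) and optionally
#' differences a cumulative series into daily new reads.
#'
#' @param data A data.frame with columns `date` and `reads` (and optionally
#'   `topic_id`).
#' @param cumulative If `TRUE`, `reads` holds cumulative reading quantity and
#'   daily differences are taken (the first day keeps its own value).
#' @return A `reading_series` pooled by day.
#' @export
as_reading_series <- function(data, cumulative = FALSE) {
  if (!all(c("date", "reads") %in% names(data))) {
    stop_bad_arg("data", "have columns `date` and `reads`")
  }
  d <- data.frame(date = as.Date(data$date), reads = as.numeric(data$reads))
  d <- d[order(d$date), , drop = FALSE]
  pooled <- stats::aggregate(reads ~ date, data = d, FUN = sum)
  if (cumulative) {
    pooled$reads <- c(pooled$reads[1L], diff(pooled$reads))
    if (any(pooled$reads < 0)) {
      stop_bad_arg("data", "be non-decreasing when cumulative = TRUE")
    }
  }
  reading_series(pooled$date, pooled$reads)
}

#' Define propagation stages
#'
#' @param name Stage names (e.g. ferment, evolution, transmission).
#' @param start,end Inclusive stage boundary dates.
#' @return An object of class `stage_definitions`.
#' @export
stage_definitions <- function(name, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (length(name) != length(start) || length(name) != length(end)) {
    stop_bad_arg("name", "match the lengths of `start` and `end`")
  }
  if (any(start > end)) stop_bad_arg("start", "be <= `end` for every stage")
  o <- order(start)
  if (length(start) > 1L && any(start[o][-1L] <= end[o][-length(end)])) {
    stop("stages must not overlap", call. = FALSE)
  }
  structure(data.frame(name = as.character(name), start = start, end = end),
            class = c("stage_definitions", "data.frame"))
}

#' The default three propagation stages
#'
#' Ferment (late January to June), evolution (July) and transmission (August
#' to early October) periods of the 2020 vaccine discourse; boundary dates are
#' configuration and may be replaced freely.
#'
#' @param year Calendar year the month-level boundaries refer to.
#' @return A [stage_definitions()] with three rows.
#' @export
default_stages <- function(year = 2020) {
  stage_definitions(
    name = c("ferment", "evolution", "transmission"),
    start = as.Date(sprintf(c("%d-01-25", "%d-07-01", "%d-08-01"), year)),
    end = as.Date(sprintf(c("%d-06-30", "%d-07-31", "%d-10-10"), year))
  )
}

#' Split a reading series into propagation stages
#'
#' Each day falls in at most one stage (stages are validated as
#' non-overlapping); days outside every stage are dropped; within-stage order
#' is preserved. An empty stage yields an empty series with a warning.
#'
#' @param series A [reading_series()].
#' @param stages A [stage_definitions()].
#' @return Named list of per-stage `reading_series`, in stage order.
#' @export
segment_stages <- function(series, stages) {
  stopifnot(inherits(series, "reading_series"),
            inherits(stages, "stage_definitions"))
  out <- vector("list", nrow(stages))
  names(out) <- stages$name
  for (i in seq_len(nrow(stages))) {
    keep <- series$date >= stages$start[i] & series$date <= stages$end[i]
    if (!any(keep)) {
      warning(sprintf("stage '%s' covers no data days", stages$name[i]),
              call. = FALSE)
    }
    sub <- series[keep, , drop = FALSE]
    out[[i]] <- structure(sub, class = c("reading_series", "data.frame"))
  }
  out
}

# Data-informed starting points: the early exponential growth rate r of the
# reads satisfies r = lam * S0 - alpha with S0 ~ N, so a log-linear slope on
# the rising limb pins lam + alpha jointly; an alpha grid spans plausible
# active-reading durations, and R(0) follows from the first day's incidence
# lam * N * R(0). These anchor the multistart in the right basin.
informed_starts <- function(reads, N, lower, upper) {
  pos <- which(reads > 0)
  peak <- which.max(reads)
  rise <- pos[pos <= max(peak, 3L)]
  r_hat <- 0.1
  if (length(rise) >= 3L) {
    sl <- stats::coef(stats::lm(log(reads[rise]) ~ rise))[[2L]]
    if (is.finite(sl)) r_hat <- min(max(sl, 0.01), 5)
  }
  starts <- lapply(c(0.25, 0.5, 1, 2), function(alpha) {
    lam <- (r_hat + alpha) / N
    R0 <- max(reads[pos[1L]] / (lam * N), 1)
    c(log(lam), log(alpha), 0.3, log(R0))
  })
  do.call(rbind, lapply(starts, function(x) pmin(pmax(x, lower), upper)))
}

# Default box constraints for the free parameters of fit_srsi.
default_fit_bounds <- function(N) {
  list(
    lam = c(1e-9, 1e-2),
    alpha = c(0.02, 10),
    p = c(0, 1),
    R_init = c(0.5, 0.1 * N)
  )
}

# SSE between observed daily reads and the model's integrated daily
# new-reader flow. x is the transformed parameter vector
# (log lam, log alpha, p, log R_init). Uses the compiled fixed-step RK4
# incidence kernel (step 0.02 day), whose discretisation error is orders of
# magnitude below the count noise in any data worth fitting.
srsi_fit_objective <- function(x, reads, N) {
  pred <- srsi_incidence_rk4(exp(x[1L]), exp(x[2L]), x[3L], exp(x[4L]),
                             N, length(reads))
  sse <- sum((reads - pred)^2)
  if (!is.finite(sse)) 1e12 * max(1, sum(reads^2)) else sse
}

#' Fit the SRS/I model to a stage's daily reading counts
#'
#' Minimises the unweighted sum of squared errors between observed daily new
#' reads and the model's new-reader flow `lam * S * R` integrated over each
#' day. Free parameters are `lam`, `alpha`, `p` and the initial reader count
#' `R(0)`; `N` is fixed by configuration and `S(0) = N - R(0)`, `I(0) = 0`
#' (N is not identifiable from a single stage). Optimisation is bounded
#' L-BFGS-B on log scales, started from a seeded Latin-hypercube multistart
#' plus the supplied initial guess, so the result is deterministic given
#' (data, guess, bounds, seed).
#'
#' @param series A [reading_series()] with at least 5 points.
#' @param N Population size; must be at least the cumulative reads.
#' @param init_guess Optional [srsi_params()] used as one of the starts.
#' @param bounds Optional named list with elements `lam`, `alpha`, `p`,
#'   `R_init`, each a `c(lower, upper)` pair; defaults via an internal rule.
#' @param n_starts Number of Latin-hypercube starts (default 8).
#' @param seed Seed for the multistart design.
#' @return An object of class `srsi_fit`: estimated `params`, `S0_hat`,
#'   `R_init_hat`, `r0_hat = lam * S0_hat / alpha`, `sse`, `sse_init`,
#'   `converged`, `n_points`.
#' @export
fit_srsi <- function(series, N, init_guess = NULL, bounds = NULL,
                     n_starts = 8L, seed = 1L) {
  stopifnot(inherits(series, "reading_series"))
  reads <- series$reads
  if (length(reads) < 5L) stop_bad_arg("series", "have at least 5 points")
  if (all(reads == 0)) {
    stop("degenerate input: the reading series is identically zero", call. = FALSE)
  }
  if (N < max(reads)) stop_bad_arg("N", "be >= the largest daily read count")
  b <- utils::modifyList(default_fit_bounds(N), bounds %||% list())
  # Cumulative reads may exceed N when re-entry is allowed (each re-entering
  # user reads again), so the population check caps unique readers only:
  # at most N/(1 - p_max) total reads are explainable under the bounds.
  p_max <- b$p[2L]
  if (p_max < 1 && sum(reads) > N / (1 - p_max)) {
    stop_bad_arg("N", "be large enough to explain the cumulative reads under the p bounds")
  }
  lower <- c(log(b$lam[1L]), log(b$alpha[1L]), b$p[1L], log(b$R_init[1L]))
  upper <- c(log(b$lam[2L]), log(b$alpha[2L]), b$p[2L], log(b$R_init[2L]))

  starts <- with_seed(seed, {
    u <- lhs::randomLHS(as.integer(n_starts), 4L)
    sweep(sweep(u, 2L, upper - lower, `*`), 2L, lower, `+`)
  })
  starts <- rbind(informed_starts(reads, N, lower, upper), starts)
  sse_init <- NA_real_
  if (!is.null(init_guess)) {
    stopifnot(inherits(init_guess, "srsi_params"))
    x0 <- c(log(init_guess$lam), log(init_guess$alpha), init_guess$p,
            log(max(b$R_init[1L], min(b$R_init[2L], max(reads[1L], 1)))))
    x0 <- pmin(pmax(x0, lower), upper)
    starts <- rbind(x0, starts)
    sse_init <- srsi_fit_objective(x0, reads, N)
  }

  # Stage 1: cheap bounded quasi-Newton descent from every start.
  cand <- list()
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], srsi_fit_objective, reads = reads, N = N,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 300L)),
      error = function(e) NULL
    )
    if (!is.null(fit)) cand[[length(cand) + 1L]] <- fit
  }
  if (length(cand) == 0L) {
    stop("optimizer failed from every start; inspect the series and bounds",
         call. = FALSE)
  }
  # Stage 2: derivative-free refinement of the leading candidates. The SSE
  # surface has narrow curved valleys where finite-difference gradients stall
  # L-BFGS-B far from the optimum; Nelder-Mead crosses them reliably.
  clamp <- function(x) pmin(pmax(x, lower), upper)
  proj_obj <- function(x) srsi_fit_objective(clamp(x), reads, N)
  ord <- order(vapply(cand, `[[`, numeric(1), "value"))
  for (i in utils::head(ord, 3L)) {
    nm <- tryCatch(
      stats::optim(cand[[i]]$par, proj_obj, method = "Nelder-Mead",
                   control = list(maxit = 1500L, reltol = 1e-9)),
      error = function(e) NULL
    )
    if (!is.null(nm)) {
      nm$par <- clamp(nm$par)
      cand[[length(cand) + 1L]] <- nm
    }
  }
  vals <- vapply(cand, `[[`, numeric(1), "value")
  best <- cand[[which.min(vals)]]
  converged <- best$convergence == 0L
  # Stage 3: tight polish from the overall best point; its termination
  # status is the convergence verdict for the whole fit. A collapsed simplex
  # (code 10) is cured by one restart from the polished point.
  for (attempt in 1:2) {
    polish <- tryCatch(
      stats::optim(clamp(best$par), proj_obj, method = "Nelder-Mead",
                   control = list(maxit = 2000L, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (is.null(polish) || polish$value > best$value) break
    polish$par <- clamp(polish$par)
    converged <- polish$convergence == 0L
    best <- polish
    if (converged) break
  }
  x <- best$par
  lam <- exp(x[1L]); alpha <- exp(x[2L]); p_hat <- x[3L]; R0 <- exp(x[4L])
  S0_hat <- N - R0
  params <- srsi_params(lam = lam, alpha = alpha, p = p_hat, N = N)
  structure(
    list(params = params, S0_hat = S0_hat, R_init_hat = R0,
         r0_hat = lam * S0_hat / alpha, sse = best$value, sse_init = sse_init,
         converged = converged, n_points = length(reads),
         n_starts = nrow(starts), seed = seed),
    class = "srsi_fit"
  )
}

#' @export
print.srsi_fit <- function(x, ...) {
  cat(sprintf(
    "SRS/I fit: r0_hat = %.4f (lam = %.3g, alpha = %.3g, p = %.3g, R(0) = %.3g)\n",
    x$r0_hat, x$params$lam, x$params$alpha, x$params$p, x$R_init_hat))
  cat(sprintf("  sse = %.6g over %d points; converged: %s\n",
              x$sse, x$n_points, x$converged))
  invisible(x)
}

#' Per-stage reproduction ratios of a reading series
#'
#' Segments the series into the given stages and fits the SRS/I model to each
#' non-empty stage. A stage that fails to fit is reported with
#' `converged = FALSE` and an `error` message; it does not abort the others.
#'
#' @inheritParams fit_srsi
#' @param stages A [stage_definitions()].
#' @return Named list of `srsi_fit` results (or failure stubs), in stage order.
#' @export
stage_reproduction_ratios <- function(series, stages, N, init_guess = NULL,
                                      bounds = NULL, n_starts = 8L, seed = 1L) {
  pieces <- segment_stages(series, stages)
  out <- vector("list", length(pieces))
  names(out) <- names(pieces)
  for (i in seq_along(pieces)) {
    out[[i]] <- tryCatch(
      fit_srsi(pieces[[i]], N = N, init_guess = init_guess, bounds = bounds,
               n_starts = n_starts, seed = seed + i - 1L),
      error = function(e) {
        list(r0_hat = NA_real_, converged = FALSE,
             n_points = nrow(pieces[[i]]), error = conditionMessage(e))
      }
    )
  }
  out
}

#' Monte-Carlo recovery study for the reproduction ratio
#'
#' Simulates noisy stage series at known reproduction ratios and refits each
#' replicate, quantifying how well `r0_hat` recovers the generating value
#' under Poisson count noise. Defaults describe a 60-day stage in a population
#' of 1e5 with mean active-reading duration of one day and re-entry
#' probability 0.3, seeded from 10 initial readers.
#'
#' @param r0_true Generating reproduction ratios, one stage per value.
#' @param n_rep Replicates per stage.
#' @param n_days Stage length in days.
#' @param N Population size.
#' @param alpha,p,R_init Generating inactivation rate, re-entry probability
#'   and initial reader count.
#' @param n_starts Multistart size passed to [fit_srsi()].
#' @param seed Master seed; replicate seeds are derived from it.
#' @return A data.frame with one row per (stage, replicate): `r0_true`,
#'   `r0_hat`, `rel_err`, `converged`.
#' @export
r0_recovery_study <- function(r0_true = c(1.14, 2.83, 3.07), n_rep = 50L,
                              n_days = 60L, N = 1e5, alpha = 1, p = 0.3,
                              R_init = 10, n_starts = 8L, seed = 1L) {
  rows <- vector("list", length(r0_true) * n_rep)
  k <- 0L
  for (j in seq_along(r0_true)) {
    S0 <- N - R_init
    lam <- r0_true[j] * alpha / S0
    params <- srsi_params(lam = lam, alpha = alpha, p = p, N = N)
    init <- srsi_state(S = S0, R = R_init, I = 0)
    for (r in seq_len(n_rep)) {
      rep_seed <- (as.numeric(seed) * 1000 + j * 100 + r) %% .Machine$integer.max
      gen <- gen_reading_series(params, init, 0:n_days, noise = "poisson",
                                seed = rep_seed)
      fit <- fit_srsi(gen$series, N = N, n_starts = n_starts, seed = rep_seed)
      k <- k + 1L
      rows[[k]] <- data.frame(
        stage = j, rep = r, r0_true = r0_true[j], r0_hat = fit$r0_hat,
        rel_err = abs(fit$r0_hat - r0_true[j]) / r0_true[j],
        converged = fit$converged
      )
    }
  }
  do.call(rbind, rows)
}
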