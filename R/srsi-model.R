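#' Parameters of the SRS/I reading-dynamics model
#'
#' The SRS/I (susceptible-reading-susceptible/immune) model describes how a
#' population of platform users moves through three states while a topic
#' circulates: susceptible users (S) who have not yet read it, active readers
#' (R) who expose their contacts to it, and immunized users (I) who have read
#' it and dropped out. New readers appear at rate `lam * S * R`, where
#' `lam = beta * k_avg` is the product of the per-contact exposure rate and the
#' mean degree of the dissemination network. Readers deactivate at rate
#' `alpha` (so `1/alpha` is the mean active-reading duration, in days); a
#' deactivating reader re-enters the susceptible state with probability `p`
#' and becomes immune with probability `1 - p`.
#'
#' Only the product `beta * k_avg` enters the dynamics, so `lam` is the
#' canonical parameter; `beta` and `k_avg` may be stored as optional
#' decorations and are checked for consistency when both are given.
#'
#' @param lam Effective transmission coefficient per (reader x susceptible)
#'   per day. May be omitted when `beta` and `k_avg` are both supplied.
#' @param alpha Inactivation rate per day; must be positive.
#' @param p Re-entry probability in `[0, 1]`.
#' @param N Total population size (persons).
#' @param beta Optional per-contact exposure rate.
#' @param k_avg Optional mean degree of the dissemination network.
#' @return An object of class `srsi_params`.
#' @examples
#' srsi_params(lam = 2e-5, alpha = 1, p = 0.3, N = 1e5)
#' @export
srsi_params <- function(lam = NULL, alpha, p, N, beta = NULL, k_avg = NULL) {
  if (is.null(lam)) {
    if (is.null(beta) || is.null(k_avg)) {
      stop_bad_arg("lam", "be supplied, or both `beta` and `k_avg`")
    }
    lam <- beta * k_avg
  }
  if (!is_scalar_number(lam) || lam < 0) stop_bad_arg("lam", "be a single number >= 0")
  if (!is_scalar_number(alpha) || alpha <= 0) stop_bad_arg("alpha", "be a single number > 0")
  if (!is_scalar_number(p) || p < 0 || p > 1) stop_bad_arg("p", "lie in [0, 1]")
  if (!is_scalar_number(N) || N <= 0) stop_bad_arg("N", "be a single number > 0")
  if (!is.null(beta) && !is.null(k_avg)) {
    if (abs(lam - beta * k_avg) > 1e-12 * max(1, abs(lam))) {
      stop_bad_arg("lam", "equal beta * k_avg when beta and k_avg are supplied")
    }
  }
  structure(
    list(lam = lam, alpha = alpha, p = p, N = N, beta = beta, k_avg = k_avg),
    class = "srsi_params"
  )
}

#' @export
print.srsi_params <- function(x, ...) {
  cat("SRS/I parameters\n")
  cat(sprintf("  lam   = %g  (per reader x susceptible per day)\n", x$lam))
  if (!is.null(x$beta)) cat(sprintf("    beta = %g, <k> = %g\n", x$beta, x$k_avg))
  cat(sprintf("  alpha = %g  (per day; mean reading duration %.3g days)\n",
              x$alpha, 1 / x$alpha))
  cat(sprintf("  p     = %g  (re-entry probability)\n", x$p))
  cat(sprintf("  N     = %g  (population)\n", x$N))
  invisible(x)
}

#' Construct an SRS/I state
#'
#' @param S,R,I Compartment counts (persons); all non-negative.
#' @param t Time in days.
#' @return An object of class `srsi_state`.
#' @export
srsi_state <- function(S, R, I, t = 0) {
  for (nm in c("S", "R", "I")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0) stop_bad_arg(nm, "be a single number >= 0")
  }
  if (!is_scalar_number(t)) stop_bad_arg("t", "be a single finite number")
  structure(list(S = S, R = R, I = I, t = t), class = "srsi_state")
}

#' Instantaneous rates of the SRS/I model
#'
#' Right-hand sides of the reading-dynamics system:
#' `dS/dt = -lam*S*R + p*alpha*R`, `dR/dt = lam*S*R - alpha*R`,
#' `dI/dt = (1-p)*alpha*R`. The three rates sum to zero, so total population
#' is conserved by construction.
#'
#' @param state An [srsi_state()] (or a list with elements S, R, I).
#' @param params An [srsi_params()].
#' @return Named numeric vector `c(dS, dR, dI)`.
#' @examples
#' p <- srsi_params(lam = 2e-4, alpha = 0.5, p = 0.4, N = 1e4)
#' srsi_derivatives(srsi_state(S = 9000, R = 1000, I = 0), p)
#' @export
srsi_derivatives <- function(state, params) {
  stopifnot(inherits(params, "srsi_params"))
  S <- state$S; R <- state$R; I <- state$I
  if (any(c(S, R, I) < 0)) stop_bad_arg("state", "have non-negative compartments")
  new_readers <- params$lam * S * R
  inactivations <- params$alpha * R
  dS <- -new_readers + params$p * inactivations
  dR <- new_readers - inactivations
  dI <- (1 - params$p) * inactivations
  c(dS = dS, dR = dR, dI = dI)
}

# deSolve-compatible rhs; y = c(S, R, I, C) where C accumulates new readers
# (dC/dt = lam*S*R), used for daily incidence.
srsi_rhs <- function(t, y, parms) {
  flow <- parms$lam * y[1L] * y[2L]
  inact <- parms$alpha * y[2L]
  list(c(
    -flow + parms$p * inact,
    flow - inact,
    (1 - parms$p) * inact,
    flow
  ))
}

#' Simulate the SRS/I model
#'
#' Integrates the deterministic mean-field system with an adaptive solver
#' (`deSolve::ode`, lsoda, `rtol = 1e-8`, `atol = 1e-8 * N`). The returned
#' trajectory is checked for conservation (`|S+R+I-N| < 1e-6 * N` at every
#' grid point) and for negativity beyond solver tolerance; either violation
#' is an error, never silently clipped.
#'
#' @param params An [srsi_params()].
#' @param init An [srsi_state()]; `S + R + I` must equal `params$N`.
#' @param t_grid Strictly increasing times in days.
#' @return An object of class `srsi_trajectory`: a data.frame with columns
#'   `t`, `S`, `R`, `I` (and cumulative new readers `C`), with the parameters
#'   attached as attribute `params`.
#' @examples
#' p <- srsi_params(lam = 3e-5, alpha = 0.4, p = 0.3, N = 1e5)
#' traj <- simulate_srsi(p, srsi_state(S = 1e5 - 10, R = 10, I = 0), 0:60)
#' head(as.data.frame(traj))
#' @export
simulate_srsi <- function(params, init, t_grid) {
  stopifnot(inherits(params, "srsi_params"))
  if (!is.numeric(t_grid) || length(t_grid) < 2L || any(diff(t_grid) <= 0)) {
    stop_bad_arg("t_grid", "be strictly increasing with at least two points")
  }
  N <- params$N
  tot0 <- init$S + init$R + init$I
  if (abs(tot0 - N) > 1e-8 * N) {
    stop_bad_arg("init", "satisfy S + R + I == params$N")
  }
  y0 <- c(S = init$S, R = init$R, I = init$I, C = 0)
  sol <- tryCatch(
    deSolve::ode(y = y0, times = t_grid, func = srsi_rhs, parms = params,
                 method = "lsoda", rtol = 1e-8, atol = 1e-8 * N),
    warning = function(w) {
      stop(sprintf("SRS/I integration failed over [%g, %g]: %s",
                   min(t_grid), max(t_grid), conditionMessage(w)), call. = FALSE)
    }
  )
  out <- as.data.frame(sol)
  names(out)[1L] <- "t"
  if (nrow(out) < length(t_grid)) {
    stop(sprintf("SRS/I integration stopped early at t = %g", max(out$t)),
         call. = FALSE)
  }
  cons <- max(abs(out$S + out$R + out$I - N))
  if (cons > 1e-6 * N) {
    stop(sprintf("conservation violated: max |S+R+I-N| = %g", cons), call. = FALSE)
  }
  neg <- min(out$S, out$R, out$I)
  if (neg < -1e-9 * N) {
    stop(sprintf("negative compartment beyond tolerance: %g", neg), call. = FALSE)
  }
  structure(out, class = c("srsi_trajectory", "data.frame"),
            params = params, init = init)
}

#' @export
print.srsi_trajectory <- function(x, ...) {
  cat(sprintf("SRS/I trajectory: %d time points over [%g, %g] days\n",
              nrow(x), min(x$t), max(x$t)))
  print.data.frame(utils::head(x, 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Daily new-reader counts of a simulated trajectory
#'
#' Integrates the new-reader flow `lam * S * R` over each interval of
#' `t_grid`, giving the model's incidence-like series (new reads per day on a
#' daily grid).
#'
#' @inheritParams simulate_srsi
#' @return Numeric vector of length `length(t_grid) - 1`.
#' @export
srsi_daily_incidence <- function(params, init, t_grid) {
  traj <- simulate_srsi(params, init, t_grid)
  diff(traj$C)
}

#' Public-opinion reproduction ratio
#'
#' The expected number of secondary readers recruited by one active reader at
#' topic launch: `R0 = lam * S0 / alpha`, derived from the initial growth
#' condition `R'(0) = (lam * S0 - alpha) * R(0)`. Reading activity grows from
#' its initial level if and only if `R0 > 1`.
#'
#' @param params An [srsi_params()].
#' @param S0 Susceptible count at topic launch, in `[0, N]`.
#' @return Dimensionless ratio.
#' @examples
#' reproduction_ratio(srsi_params(lam = 2e-5, alpha = 1, p = 0.3, N = 2e5), S0 = 1e5)
#' @export
reproduction_ratio <- function(params, S0) {
  stopifnot(inherits(params, "srsi_params"))
  if (!is_scalar_number(S0) || S0 < 0 || S0 > params$N) {
    stop_bad_arg("S0", "lie in [0, N]")
  }
  params$lam * S0 / params$alpha
}

#' Write a trajectory to CSV with a JSON parameter sidecar
#'
#' @param traj An `srsi_trajectory`.
#' @param path Output CSV path (columns `t, S, R, I`); the parameters are
#'   echoed to `<path without extension>_params.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "srsi_trajectory"))
  utils::write.csv(as.data.frame(traj)[, c("t", "S", "R", "I")], path,
                   row.names = FALSE)
  p <- attr(traj, "params")
  sidecar <- paste0(tools::file_path_sans_ext(path), "_params.json")
  jsonlite::write_json(
    list(lam = p$lam, alpha = p$alpha, p = p$p, N = p$N,
         beta = p$beta, k_avg = p$k_avg),
    sidecar, auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(sidecar)
}
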