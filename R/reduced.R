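# Reduced double-bind model: two logistic populations sharing one
# carrying capacity, radiotherapy as a fractional growth-rate reduction
# (delta) on sensitive cells, and an NK kill effect of total rate lambda
# split between the populations by the double-bind parameter B.
#
# dS/dt = r_S (1 - delta * rt) S (1 - (S+R)/K) - lambda S (1-B) nk
# dR/dt = r_R R (1 - (R+S)/K)                  - lambda R B nk
#
# B = 0 aims the second treatment entirely at sensitive cells, B = 1
# entirely at resistant cells. Units here are raw cells (K ~ 1e5) and
# hours.

#' Construct a reduced-model parameter set
#'
#' `r_R` is derived from the cost-of-resistance fraction `c` as
#' `r_S * (1 - c)` unless given explicitly.
#'
#' @param r_S Sensitive growth rate, per hour.
#' @param c Cost-of-resistance fraction in \[0, 1); ignored when `r_R`
#'   is supplied.
#' @param r_R Resistant growth rate, per hour (optional).
#' @param K Shared carrying capacity, cells (> 0).
#' @param delta Radiotherapy dose-effect fraction (may exceed 1: net
#'   kill).
#' @param lambda Total NK kill rate, per hour.
#' @param B Double-bind parameter in \[0, 1\].
#' @return An object of class `reduced_params`.
#' @export
reduced_parameter_set <- function(r_S = 0.032, c = 0.1, r_R = NULL,
                                  K = 1e5, delta = 0.5,
                                  lambda = 0.05, B = 0.5) {
  if (K <= 0) stop("K must be positive", call. = FALSE)
  if (B < 0 || B > 1) stop("B must lie in [0, 1]", call. = FALSE)
  if (is.null(r_R)) {
    r_R <- cost_to_rate(r_S, c)
  } else {
    c <- if (r_S > 0) 1 - r_R / r_S else NA_real_
  }
  p <- list(r_S = r_S, r_R = r_R, c = c, K = K, delta = delta,
            lambda = lambda, B = B)
  class(p) <- "reduced_params"
  p
}

#' Resistant growth rate under a cost of resistance
#'
#' @param r_S Sensitive growth rate, per hour.
#' @param c Cost fraction in \[0, 1).
#' @return `r_R = r_S * (1 - c)`.
#' @export
cost_to_rate <- function(r_S, c) {
  if (c < 0 || c >= 1) stop("c must lie in [0, 1)", call. = FALSE)
  r_S * (1 - c)
}

#' Instantaneous rates of the reduced model
#'
#' @param S,R Nonnegative abundances, cells.
#' @param params A `reduced_params` object.
#' @param rt_on,nk_on Logical flags: is each treatment being applied?
#' @param literal_kill If `TRUE`, use the alternative form in which the
#'   kill flux on R is proportional to S (`lambda * S * B`) rather than
#'   to R; kept for auditability, see the methods vignette.
#' @return Numeric vector `c(dS, dR)`, cells per hour.
#' @export
reduced_rates <- function(S, R, params, rt_on = FALSE, nk_on = FALSE,
                          literal_kill = FALSE) {
  stopifnot(inherits(params, "reduced_params"))
  if (params$K <= 0) stop("K must be positive", call. = FALSE)
  if (any(c(S, R) < 0)) stop("S and R must be nonnegative", call. = FALSE)
  rt <- as.numeric(rt_on); nk <- as.numeric(nk_on)
  logistic <- 1 - (S + R) / params$K
  dS <- params$r_S * (1 - params$delta * rt) * S * logistic -
    params$lambda * S * (1 - params$B) * nk
  kill_R <- if (literal_kill) params$lambda * S * params$B
  else params$lambda * R * params$B
  dR <- params$r_R * R * logistic - kill_R * nk
  c(dS = dS, dR = dR)
}

#' Simulate the reduced model
#'
#' Treatment flags are constant over a run (continuous dosing);
#' sequential schedules are composed by chaining runs with state
#' hand-off.
#'
#' @param params A `reduced_params` object.
#' @param init Named vector with `S` and `R` initial abundances, cells.
#' @param times Output times (hours), increasing from 0.
#' @param rt_on,nk_on Treatment flags.
#' @param literal_kill See [reduced_rates()].
#' @param rtol,atol Solver tolerances.
#' @return Data frame with columns `time_h`, `S`, `R`.
#' @export
simulate_reduced <- function(params, init = c(S = 900, R = 100),
                             times = seq(0, 500, by = 2),
                             rt_on = FALSE, nk_on = FALSE,
                             literal_kill = FALSE,
                             rtol = 1e-8, atol = 1e-10) {
  init <- as.list(init)
  rhs <- function(t, y, parms) {
    list(reduced_rates(y[1L], y[2L], params, rt_on, nk_on, literal_kill))
  }
  sol <- deSolve::ode(y = c(S = init$S, R = init$R), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  out <- as.data.frame(unclass(sol))
  names(out) <- c("time_h", "S", "R")
  out$S[out$S < 0] <- 0
  out$R[out$R < 0] <- 0
  out
}

sweep_finalize <- function(values, finals, value_name) {
  out <- data.frame(sweep_value = values,
                    final_S = vapply(finals, `[[`, 0, "S"),
                    final_R = vapply(finals, `[[`, 0, "R"))
  out$resistant_fraction <- out$final_R / pmax(out$final_S + out$final_R,
                                               .Machine$double.eps)
  attr(out, "swept") <- value_name
  out
}

#' Sweep the radiotherapy dose-effect fraction
#'
#' Simulates the reduced model under continuous radiotherapy for each
#' `delta` and records the final state. Increasing dose suppresses the
#' sensitive population and selects for resistance: on the default grid
#' `delta = 0.5, 1, 1.5, 2, 2.5` the final S is non-increasing and the
#' final resistant fraction non-decreasing.
#'
#' @param deltas Ascending dose-effect fractions.
#' @param params A `reduced_params` object (its `delta` is overridden).
#' @param horizon Simulation length, hours.
#' @param init Initial `c(S, R)`, cells.
#' @param nk_on Also apply NK therapy during the sweep?
#' @return Data frame `sweep_value, final_S, final_R,
#'   resistant_fraction`.
#' @export
sweep_delta <- function(deltas = c(0.5, 1, 1.5, 2, 2.5),
                        params = reduced_parameter_set(),
                        horizon = 500, init = c(S = 900, R = 100),
                        nk_on = FALSE) {
  if (is.unsorted(deltas)) stop("deltas must be ascending", call. = FALSE)
  finals <- lapply(deltas, function(d) {
    p <- params; p$delta <- d
    tr <- simulate_reduced(p, init, times = seq(0, horizon, length.out = 251),
                           rt_on = TRUE, nk_on = nk_on)
    tr[nrow(tr), c("S", "R")]
  })
  sweep_finalize(deltas, finals, "delta")
}

#' Sweep the double-bind parameter
#'
#' Simulates the reduced model under NK therapy (with radiotherapy on by
#' default) for each `B` and records the final state. The final
#' sensitive population is non-decreasing and the final resistant
#' population non-increasing in B: a stronger double bind redirects the
#' NK kill effect from S to R.
#'
#' @param b_grid Values of B in \[0, 1\].
#' @param params A `reduced_params` object (its `B` is overridden).
#' @param horizon Simulation length, hours.
#' @param init Initial `c(S, R)`, cells.
#' @param rt_on Also apply radiotherapy during the sweep?
#' @return Data frame `sweep_value, final_S, final_R,
#'   resistant_fraction`.
#' @export
sweep_B <- function(b_grid = seq(0, 1, by = 0.1),
                    params = reduced_parameter_set(),
                    horizon = 500, init = c(S = 900, R = 100),
                    rt_on = TRUE) {
  if (any(b_grid < 0 | b_grid > 1))
    stop("b_grid must lie in [0, 1]", call. = FALSE)
  finals <- lapply(b_grid, function(b) {
    p <- params; p$B <- b
    tr <- simulate_reduced(p, init, times = seq(0, horizon, length.out = 251),
                           rt_on = rt_on, nk_on = TRUE)
    tr[nrow(tr), c("S", "R")]
  })
  sweep_finalize(b_grid, finals, "B")
}
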