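# Three-population Lotka-Volterra competition model with NK killing.
#
# dS/dt = r_S * S * (1 - (S + alpha_SR * R) / K_S) - lambda_SN * S * N
# dR/dt = r_R * R * (1 - (R + alpha_RS * S) / K_R) - lambda_RN * R * N
# dN/dt = r_N * N * (1 - N / K_N)
#
# Units: time in hours, abundances in 1e5 cells.

#' Instantaneous rates of the full model
#'
#' Evaluates the right-hand side of the three coupled ODEs at a single
#' state. Sensitive (S) and resistant (R) tumour cells compete
#' logistically through the coefficients `alpha_SR`, `alpha_RS`; NK
#' cells (N) grow logistically with no feedback from the tumour and kill
#' S and R at per-capita rates `lambda_SN * N` and `lambda_RN * N`.
#'
#' @param state Named numeric vector or list with components `S`, `R`,
#'   `N` (1e5 cells), all nonnegative.
#' @param params An `lv_params` object, see [parameter_set()].
#' @return Named numeric vector `c(dS, dR, dN)` in 1e5 cells per hour.
#' @examples
#' p <- parameter_set(r_S = 0.032, K_S = 1.27, alpha_SR = 1.54)
#' lv_rates(c(S = 0.5, R = 0.5, N = 0), p)  # dS = 0: S + 1.54 R = K_S
#' @export
lv_rates <- function(state, params) {
  validate_parameter_set(params)
  state <- as.list(state)
  if (!all(c("S", "R", "N") %in% names(state)))
    stop("state must have components S, R, N", call. = FALSE)
  S <- state$S; R <- state$R; N <- state$N
  if (any(c(S, R, N) < 0))
    stop("state components must be nonnegative", call. = FALSE)
  dS <- params$r_S * S * (1 - (S + params$alpha_SR * R) / params$K_S) -
    params$lambda_SN * S * N
  dR <- params$r_R * R * (1 - (R + params$alpha_RS * S) / params$K_R) -
    params$lambda_RN * R * N
  dN <- params$r_N * N * (1 - N / params$K_N)
  c(dS = dS, dR = dR, dN = dN)
}

# deSolve RHS for a bank of wells sharing one parameter set. The state
# stacks S and R for each well plus a single shared N channel (N receives
# no tumour feedback, so identical wells share one NK trajectory).
lv_rhs_stacked <- function(t, y, parms) {
  n <- parms$n_wells
  S <- y[seq_len(n)]
  R <- y[n + seq_len(n)]
  N <- y[2L * n + 1L]
  dS <- parms$r_S * S * (1 - (S + parms$alpha_SR * R) / parms$K_S) -
    parms$lambda_SN * S * N
  dR <- parms$r_R * R * (1 - (R + parms$alpha_RS * S) / parms$K_R) -
    parms$lambda_RN * R * N
  dN <- parms$r_N * N * (1 - N / parms$K_N)
  # numerical safeguard: mutually negative competition coefficients
  # admit finite-time blow-up; taper positive growth to zero far above
  # the admissible capacity range (K <= 10) so trial parameter sets
  # during optimization cannot overflow the integrator. The taper only
  # acts above 1e8 cells, orders of magnitude beyond any data.
  cap <- 1e3
  w <- pmax(0, pmin(1, (1.1 * cap - S) / (0.1 * cap)))
  dS <- ifelse(dS > 0, dS * w, dS)
  w <- pmax(0, pmin(1, (1.1 * cap - R) / (0.1 * cap)))
  dR <- ifelse(dR > 0, dR * w, dR)
  list(c(dS, dR, dN))
}

# Integrate a bank of wells (rows of `inits` = wells with columns S, R)
# sharing one parameter set and one N(0). Returns a list with matrices
# S, R (time x well) and vector N.
simulate_wells <- function(params, inits, N0, times,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(is.matrix(inits), ncol(inits) == 2L)
  n <- nrow(inits)
  y0 <- c(inits[, 1L], inits[, 2L], N0)
  parms <- c(params[lv_param_names()], list(n_wells = n))
  sol <- suppressWarnings(
    deSolve::ode(y = y0, times = times, func = lv_rhs_stacked,
                 parms = parms, method = "lsoda",
                 rtol = rtol, atol = atol))
  if (nrow(sol) < length(times) || any(!is.finite(unclass(sol))))
    stop("ODE integration failed (solver returned early or non-finite ",
         "states)", call. = FALSE)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed to converge (lsoda istate ",
         attr(sol, "istate")[1L], ")", call. = FALSE)
  out <- unclass(sol)[, -1L, drop = FALSE]
  # per-capita rates are finite at zero so trajectories stay nonnegative
  # analytically; clip solver undershoot below tolerance
  out[out < 0 & out > -atol * 100] <- 0
  out[out < 0] <- 0
  list(S = out[, seq_len(n), drop = FALSE],
       R = out[, n + seq_len(n), drop = FALSE],
       N = out[, 2L * n + 1L])
}

#' Simulate the full model
#'
#' Integrates the three-population system with an adaptive solver
#' (`deSolve::ode`, lsoda) from a nonnegative initial state over a
#' strictly increasing time grid starting at 0. Negative solver
#' undershoot is clipped to zero.
#'
#' @param params An `lv_params` object.
#' @param init Named vector or list with `S`, `R`, `N` initial
#'   abundances (1e5 cells).
#' @param times Numeric vector of output times (hours), strictly
#'   increasing with `times[1] == 0`.
#' @param rtol,atol Solver tolerances.
#' @return A data frame of class `lv_trajectory` with columns `time_h`,
#'   `S`, `R`, `N`.
#' @examples
#' p <- parameter_set(r_N = 0.0178, K_N = 1)
#' tr <- simulate_lv(p, c(S = 0, R = 0, N = 0.1), seq(0, 100, 10))
#' tail(tr, 1)  # ~ logistic_closed_form(0.0178, 1, 0.1, 100)
#' @export
simulate_lv <- function(params, init, times, rtol = 1e-8, atol = 1e-10) {
  validate_parameter_set(params)
  init <- as.list(init)
  if (!all(c("S", "R", "N") %in% names(init)))
    stop("init must have components S, R, N", call. = FALSE)
  if (any(unlist(init[c("S", "R", "N")]) < 0))
    stop("initial state must be nonnegative", call. = FALSE)
  if (length(times) < 2L || any(diff(times) <= 0) || times[1L] != 0)
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  sim <- simulate_wells(params, matrix(c(init$S, init$R), nrow = 1L),
                        init$N, times, rtol = rtol, atol = atol)
  tr <- data.frame(time_h = times, S = sim$S[, 1L], R = sim$R[, 1L],
                   N = sim$N)
  class(tr) <- c("lv_trajectory", "data.frame")
  tr
}

#' Closed-form logistic growth
#'
#' The NK channel decouples from the tumour populations, so its solution
#' is the textbook logistic curve
#' `K * N0 * exp(r t) / (K + N0 * (exp(r t) - 1))`. Used as an
#' independent check on the numerical integrator.
#'
#' @param r Growth rate, per hour.
#' @param K Carrying capacity (> 0).
#' @param N0 Initial abundance (>= 0).
#' @param t Time(s), hours.
#' @return Abundance at `t` (vectorized over `t`).
#' @examples
#' logistic_closed_form(0.0178, 1, 0.1, 100)  # ~0.397
#' @export
logistic_closed_form <- function(r, K, N0, t) {
  if (K <= 0) stop("K must be positive", call. = FALSE)
  if (N0 < 0) stop("N0 must be nonnegative", call. = FALSE)
  ert <- exp(r * t)
  K * N0 * ert / (K + N0 * (ert - 1))
}

#' Radiotherapy growth-rate modifier
#'
#' In the reduced model radiotherapy scales the sensitive growth rate by
#' `(1 - delta)`: `r_S' = r_S * (1 - delta)`. `delta > 1` corresponds to
#' net kill (negative effective growth).
#'
#' @param r_S Untreated sensitive growth rate, per hour.
#' @param delta Dose-effect fraction.
#' @return Modified growth rate `r_S * (1 - delta)`.
#' @seealso [delta_from_rates()] for the inverse map.
#' @export
rt_growth_modifier <- function(r_S, delta) {
  r_S * (1 - delta)
}

#' Infer the radiotherapy dose-effect fraction from paired growth rates
#'
#' Inverts [rt_growth_modifier()]: `delta = 1 - r_S_treated / r_S`.
#'
#' @param r_S Untreated sensitive growth rate (> 0), per hour.
#' @param r_S_treated Growth rate under radiotherapy, per hour.
#' @return The fraction `delta`.
#' @examples
#' delta_from_rates(0.032, 0.0162)  # ~0.494
#' @export
delta_from_rates <- function(r_S, r_S_treated) {
  if (r_S <= 0) stop("r_S must be positive", call. = FALSE)
  1 - r_S_treated / r_S
}

#' Write a trajectory to tidy CSV
#'
#' @param trajectory An `lv_trajectory` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(all(c("time_h", "S", "R", "N") %in% names(trajectory)))
  utils::write.csv(as.data.frame(trajectory)[, c("time_h", "S", "R", "N")],
                   path, row.names = FALSE)
  invisible(path)
}
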