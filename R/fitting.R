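# Staged bounded least-squares inference for the full model.
#
# One "fitting batch" is a single replicate observed across all seeding
# fractions simultaneously; the untreated arm is fit first and its mean
# carrying capacities are then fixed for every treated arm (capacities
# are poorly identified when treatment suppresses growth). K_N is always
# fixed at 1 (1e5 cells) because NK cells are never observed.

#' Configure the fitting procedure
#'
#' @param rate_bounds Bounds for growth rates, per hour.
#' @param interaction_bounds Bounds shared by the competition
#'   coefficients (alpha) and NK kill rates (lambda).
#' @param capacity_bounds Bounds for carrying capacities, 1e5 cells. The
#'   lower bound is a small positive number (capacities must be
#'   positive).
#' @param n_multistart Number of optimizer starts per replicate; the
#'   first start is a data-driven heuristic, the rest are multiplicative
#'   jitters of it.
#' @param start_jitter Two-sided multiplicative jitter range applied to
#'   the heuristic start (log-uniform in `[1/start_jitter, start_jitter]`).
#' @param ftol,ptol,maxiter Levenberg-Marquardt tolerances and iteration
#'   cap passed to [minpack.lm::nls.lm()].
#' @param seed RNG seed controlling the jittered starts.
#' @return An object of class `nk_fit_config`.
#' @export
fit_config <- function(rate_bounds = c(0, 1),
                       interaction_bounds = c(-15, 15),
                       capacity_bounds = c(1e-6, 10),
                       n_multistart = 8L,
                       start_jitter = 2,
                       ftol = 1e-10, ptol = 1e-10, maxiter = 200L,
                       seed = 1L) {
  stopifnot(rate_bounds[1] < rate_bounds[2],
            interaction_bounds[1] < interaction_bounds[2],
            capacity_bounds[1] < capacity_bounds[2],
            capacity_bounds[1] > 0,
            n_multistart >= 1, start_jitter >= 1)
  cfg <- list(rate_bounds = rate_bounds,
              interaction_bounds = interaction_bounds,
              capacity_bounds = capacity_bounds,
              n_multistart = as.integer(n_multistart),
              start_jitter = start_jitter,
              ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
              seed = as.integer(seed))
  class(cfg) <- "nk_fit_config"
  cfg
}

# Free parameters per condition under the staging rules.
condition_free_params <- function(condition, stage1 = (condition == "UT")) {
  base <- c("r_S", "r_R", "alpha_SR", "alpha_RS")
  if (stage1) base <- c(base, "K_S", "K_R")
  if (condition %in% c("NK", "RTNK"))
    base <- c(base, "r_N", "lambda_SN", "lambda_RN")
  base
}

param_bounds <- function(names, config) {
  lower <- numeric(length(names)); upper <- numeric(length(names))
  for (i in seq_along(names)) {
    nm <- names[i]
    b <- if (startsWith(nm, "r_")) config$rate_bounds
    else if (startsWith(nm, "K_")) config$capacity_bounds
    else config$interaction_bounds
    lower[i] <- b[1]; upper[i] <- b[2]
  }
  list(lower = stats::setNames(lower, names),
       upper = stats::setNames(upper, names))
}

# Reshape one (condition, replicate) slice into aligned matrices
# (time x fraction) plus the grid and fraction vector.
slice_matrices <- function(slice) {
  fr <- sort(unique(slice$f))
  times <- sort(unique(slice$time_h))
  nt <- length(times); nf <- length(fr)
  S <- matrix(NA_real_, nt, nf); R <- matrix(NA_real_, nt, nf)
  for (j in seq_along(fr)) {
    sub <- slice[slice$f == fr[j], ]
    sub <- sub[order(sub$time_h), ]
    if (nrow(sub) != nt || any(sub$time_h != times))
      stop("time grid mismatch for fraction f = ", fr[j], call. = FALSE)
    S[, j] <- sub$count_S
    R[, j] <- sub$count_R
  }
  list(S = S, R = R, times = times, fractions = fr)
}

#' Residuals of the full model against one replicate
#'
#' Concatenates (model - observation) over all fractions, all times and
#' both observed channels (S then R within each fraction). Model initial
#' conditions are derived from the design and the seeding fraction; the
#' NK channel contributes no residuals (it is unobserved).
#'
#' @param params An `lv_params` object.
#' @param slice One (condition, replicate) slice of an `nk_dataset`,
#'   covering all fractions.
#' @param design The `nk_design` that produced the data.
#' @param condition Condition code; defaults to the slice's condition.
#' @return Numeric residual vector of length
#'   `2 * n_fractions * n_times`.
#' @export
lv_residuals <- function(params, slice, design,
                         condition = unique(slice$condition)) {
  stopifnot(length(condition) == 1L)
  m <- slice_matrices(slice)
  inits <- t(vapply(m$fractions, function(f) {
    ic <- design_init(design, f, condition)
    c(ic$S, ic$R)
  }, numeric(2)))
  N0 <- design_init(design, m$fractions[1L], condition)$N
  sim <- simulate_wells(params, inits, N0, m$times)
  as.vector(rbind(sim$S - m$S, sim$R - m$R))
}

# Data-driven heuristic start: early log-slope of the monoculture
# channels for growth rates, observed plateau for capacities, neutral
# values for interactions.
heuristic_start <- function(m, condition, free, config) {
  early <- which(m$times <= m$times[1] + 30)
  if (length(early) < 3) early <- seq_len(min(5L, length(m$times)))
  slope <- function(y, idx) {
    y <- pmax(y[idx], 1e-6)
    stats::coef(stats::lm(log(y) ~ m$times[idx]))[[2L]]
  }
  clip <- function(x, b) min(max(x, b[1] + 1e-9), b[2] - 1e-9)
  jS <- which.min(m$fractions)   # most sensitive-rich well
  jR <- which.max(m$fractions)   # most resistant-rich well
  start <- c(
    r_S = clip(slope(m$S[, jS], early), config$rate_bounds),
    r_R = clip(slope(m$R[, jR], early), config$rate_bounds),
    r_N = 0.02,
    K_S = clip(max(m$S), config$capacity_bounds),
    K_R = clip(max(m$R), config$capacity_bounds),
    alpha_SR = 1, alpha_RS = 1,
    lambda_SN = 0.01, lambda_RN = 0.01)
  start[free]
}

#' Fit the full model to one replicate
#'
#' Bounded Levenberg-Marquardt least squares over the free parameters
#' of the condition, taking the best of `n_multistart` jittered starts.
#' Deterministic given `config$seed`.
#'
#' @param slice One (condition, replicate) slice of an `nk_dataset`.
#' @param condition Condition code.
#' @param config An `nk_fit_config`.
#' @param design The `nk_design` that produced the data.
#' @param fixed Named list of parameter values frozen by the staging
#'   rules (e.g. carrying capacities from the untreated stage). The
#'   structural zeros of no-NK arms and `K_N = 1` are applied
#'   automatically.
#' @return An object of class `nk_fit`: the estimated `lv_params`
#'   (fixed mask recording frozen parameters), `loss` (residual sum of
#'   squares), `converged`, per-parameter `at_bounds` flags, and the
#'   dispersion of losses across starts.
#' @export
fit_replicate <- function(slice, condition, config = fit_config(),
                          design, fixed = list()) {
  condition <- match.arg(condition, lv_conditions())
  m <- slice_matrices(slice)

  base <- list(r_S = 0.03, r_R = 0.03, r_N = 0, K_S = 1, K_R = 1, K_N = 1,
               alpha_SR = 0, alpha_RS = 0, lambda_SN = 0, lambda_RN = 0)
  auto_fixed <- list(K_N = 1)
  if (condition %in% c("UT", "RT"))
    auto_fixed <- c(auto_fixed, list(r_N = 0, lambda_SN = 0, lambda_RN = 0))
  fixed <- utils::modifyList(auto_fixed, as.list(fixed))
  free <- setdiff(condition_free_params(condition,
                                        stage1 = !("K_S" %in% names(fixed))),
                  names(fixed))
  for (nm in names(fixed)) base[[nm]] <- fixed[[nm]]

  bounds <- param_bounds(free, config)
  n_res <- 2L * length(m$times) * length(m$fractions)

  make_params <- function(theta) {
    p <- base
    for (i in seq_along(free)) p[[free[i]]] <- theta[[i]]
    p$fixed <- names(fixed)
    class(p) <- "lv_params"
    p
  }
  fn <- function(theta) {
    tryCatch(
      lv_residuals(make_params(theta), slice, design, condition),
      error = function(e) rep(1e6, n_res))
  }

  start0 <- heuristic_start(m, condition, free, config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  best <- NULL
  losses <- numeric(0)
  for (k in seq_len(config$n_multistart)) {
    start <- start0
    if (k > 1L) {
      jit <- exp(stats::runif(length(start), -log(config$start_jitter),
                              log(config$start_jitter)))
      start <- pmin(pmax(start * jit, bounds$lower + 1e-9),
                    bounds$upper - 1e-9)
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = bounds$lower,
                         upper = bounds$upper, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = config$ftol, ptol = config$ptol,
                           maxiter = config$maxiter)),
      error = function(e) NULL)
    if (is.null(res)) next
    loss <- sum(res$fvec^2)
    losses <- c(losses, loss)
    if (is.null(best) || loss < best$loss)
      best <- list(fit = res, loss = loss)
  }
  if (is.null(best))
    stop("all ", config$n_multistart, " starts failed for condition ",
         condition, call. = FALSE)

  est <- best$fit$par
  at_bounds <- abs(est - bounds$lower) < 1e-8 | abs(est - bounds$upper) < 1e-8
  names(at_bounds) <- free
  out <- list(
    condition = condition,
    replicate = unique(slice$replicate)[1L],
    params = validate_parameter_set(make_params(est)),
    free = free,
    loss = best$loss,
    converged = best$fit$info %in% 1:4,
    info = best$fit$info,
    at_bounds = at_bounds,
    multistart_spread = if (length(losses) > 1L) stats::sd(losses) else 0,
    n_starts = length(losses))
  class(out) <- "nk_fit"
  out
}

#' @export
print.nk_fit <- function(x, ...) {
  cat(sprintf("<nk_fit> %s replicate %s  loss %.4g  %s\n",
              x$condition, x$replicate, x$loss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Reconstruct a design from a dataset's provenance sidecar.
dataset_design <- function(dataset) {
  prov <- attr(dataset, "provenance")
  if (is.null(prov) || is.null(prov$design))
    stop("dataset carries no design provenance; pass `design` explicitly",
         call. = FALSE)
  d <- prov$design
  experiment_design(fractions = unlist(d$fractions),
                    n_replicates = d$n_replicates,
                    sample_interval = d$sample_interval,
                    horizon = d$horizon, tumor_seed = d$tumor_seed,
                    et_ratio = d$et_ratio,
                    conditions = unlist(d$conditions))
}

#' Staged fit of a full co-culture dataset
#'
#' Stage 1 fits every untreated replicate with growth rates, carrying
#' capacities and competition coefficients free. Stage 2 fixes `K_S` and
#' `K_R` at their untreated across-replicate means (and `K_N` at 1) and
#' fits the treated arms: RT frees growth and competition terms only;
#' NK and RT+NK additionally free `r_N`, `lambda_SN`, `lambda_RN`.
#'
#' @param dataset An `nk_dataset` containing at least the `UT`
#'   condition.
#' @param config An `nk_fit_config`.
#' @param design The producing `nk_design`; recovered from the dataset's
#'   provenance when omitted.
#' @return Named list mapping each condition present in the data to a
#'   list of `nk_fit` results (one per replicate).
#' @export
staged_fit <- function(dataset, config = fit_config(), design = NULL) {
  if (is.null(design)) design <- dataset_design(dataset)
  conds <- intersect(lv_conditions(), unique(dataset$condition))
  if (!("UT" %in% conds))
    stop("staged fit requires the untreated (UT) condition", call. = FALSE)

  fit_condition <- function(cond, fixed) {
    reps <- sort(unique(dataset$replicate[dataset$condition == cond]))
    lapply(reps, function(r) {
      slice <- dataset[dataset$condition == cond & dataset$replicate == r, ]
      fit_replicate(slice, cond, config, design, fixed = fixed)
    })
  }

  results <- list(UT = fit_condition("UT", fixed = list()))
  ut_ok <- Filter(function(f) f$converged, results$UT)
  if (!length(ut_ok))
    stop("no untreated replicate converged; cannot stage capacities",
         call. = FALSE)
  K_S_bar <- mean(vapply(ut_ok, function(f) f$params$K_S, 0))
  K_R_bar <- mean(vapply(ut_ok, function(f) f$params$K_R, 0))

  for (cond in setdiff(conds, "UT")) {
    results[[cond]] <- fit_condition(
      cond, fixed = list(K_S = K_S_bar, K_R = K_R_bar))
  }
  results[conds]
}

#' Summarize staged-fit results across replicates
#'
#' Means and standard errors (sd / sqrt(n)) per parameter per
#' condition, computed over converged replicates only; non-converged
#' replicates are dropped with a warning. Fixed parameters are reported
#' with zero SEM and `fixed = TRUE`.
#'
#' @param results Output of [staged_fit()].
#' @return A data frame of class `nk_fit_summary` with columns
#'   `condition`, `parameter`, `mean`, `sem`, `n`, `fixed`.
#' @export
summarize_fits <- function(results) {
  if (!length(results)) stop("empty results", call. = FALSE)
  rows <- list()
  for (cond in names(results)) {
    fits <- results[[cond]]
    ok <- Filter(function(f) f$converged, fits)
    if (length(ok) < length(fits))
      warning(length(fits) - length(ok), " non-converged replicate(s) ",
              "dropped for condition ", cond, call. = FALSE)
    if (!length(ok))
      stop("no converged replicate for condition ", cond, call. = FALSE)
    fixed_names <- ok[[1L]]$params$fixed
    for (nm in lv_param_names()) {
      vals <- vapply(ok, function(f) f$params[[nm]], 0)
      is_fixed <- nm %in% fixed_names
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, parameter = nm,
        mean = mean(vals),
        sem = if (is_fixed || length(vals) < 2L) 0
        else stats::sd(vals) / sqrt(length(vals)),
        n = length(ok), fixed = is_fixed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nk_fit_summary", "data.frame")
  out
}

#' Extract a mean parameter set from a fit summary
#'
#' @param summary An `nk_fit_summary`.
#' @param condition Condition code present in the summary.
#' @return An `lv_params` built from the per-parameter means.
#' @export
summary_params <- function(summary, condition) {
  sub <- summary[summary$condition == condition, ]
  if (!nrow(sub)) stop("condition ", condition, " not in summary",
                       call. = FALSE)
  vals <- as.list(stats::setNames(sub$mean, sub$parameter))
  do.call(parameter_set,
          c(vals, list(fixed = sub$parameter[sub$fixed])))
}

#' Hold-out validation of the staged fit
#'
#' Splits replicates into training and validation sets, runs the staged
#' fit on the training replicates only, and scores the held-out
#' replicates with the training across-replicate parameter means.
#' Losses are mean residual sums of squares per replicate, so training
#' and validation numbers are directly comparable.
#'
#' @param dataset An `nk_dataset`.
#' @param split Either a proportion in (0, 1) of replicates used for
#'   training, or an integer vector of training replicate ids.
#' @param config An `nk_fit_config`.
#' @param design The producing `nk_design`; from provenance when `NULL`.
#' @return A data frame with columns `condition`, `train_loss`,
#'   `validation_loss`, `n_train`, `n_validation`.
#' @export
holdout_validate <- function(dataset, split = 0.5, config = fit_config(),
                             design = NULL) {
  if (is.null(design)) design <- dataset_design(dataset)
  reps <- sort(unique(dataset$replicate))
  if (length(split) == 1L && split > 0 && split < 1) {
    n_train <- floor(length(reps) * split)
    train_ids <- reps[seq_len(n_train)]
  } else {
    train_ids <- intersect(reps, as.integer(split))
  }
  valid_ids <- setdiff(reps, train_ids)
  if (!length(train_ids) || !length(valid_ids))
    stop("degenerate split: both sides need at least one replicate",
         call. = FALSE)

  train <- dataset[dataset$replicate %in% train_ids, ]
  class(train) <- class(dataset)
  attr(train, "provenance") <- attr(dataset, "provenance")
  results <- staged_fit(train, config, design)
  summ <- summarize_fits(results)

  rows <- lapply(names(results), function(cond) {
    p_bar <- summary_params(summ, cond)
    tr_losses <- vapply(Filter(function(f) f$converged, results[[cond]]),
                        function(f) f$loss, 0)
    va_losses <- vapply(valid_ids, function(r) {
      slice <- dataset[dataset$condition == cond & dataset$replicate == r, ]
      sum(lv_residuals(p_bar, slice, design, cond)^2)
    }, 0)
    data.frame(condition = cond,
               train_loss = mean(tr_losses),
               validation_loss = mean(va_losses),
               n_train = length(tr_losses),
               n_validation = length(va_losses))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
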