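# Double-bind diagnostics from fitted parameters: differential NK kill,
# cost of resistance, and the competition-regime classification.

#' Double-bind score
#'
#' The signed excess of the NK kill rate on resistant cells over that on
#' sensitive cells, `lambda_RN - lambda_SN`. A positive score means NK
#' cells preferentially kill the radiation-resistant population — the
#' defining signature of an evolutionary double bind, where adapting to
#' radiotherapy buys increased vulnerability to NK attack.
#'
#' @param params An `lv_params` object from an NK-containing condition.
#' @return `lambda_RN - lambda_SN` (per unit N per hour). For a no-NK
#'   parameter set (both kill rates fixed at zero) a warning is issued
#'   and 0 returned.
#' @export
double_bind_score <- function(params) {
  validate_parameter_set(params)
  if (params$lambda_SN == 0 && params$lambda_RN == 0 &&
      all(c("lambda_SN", "lambda_RN") %in% params$fixed)) {
    warning("no-NK condition: kill rates fixed at zero, score is 0",
            call. = FALSE)
    return(0)
  }
  params$lambda_RN - params$lambda_SN
}

#' Cost of resistance
#'
#' The intrinsic growth-rate deficit of resistant cells, `r_S - r_R`.
#' Positive is the classical cost (resistance slows growth); negative
#' indicates a growth benefit to resistant cells.
#'
#' @param params An `lv_params` object.
#' @return `r_S - r_R` (per hour).
#' @export
cost_of_resistance <- function(params) {
  validate_parameter_set(params)
  params$r_S - params$r_R
}

#' Classify the tumour-tumour competition regime
#'
#' Under the model's sign convention a positive competition coefficient
#' inside `(x + alpha * y) / K` suppresses the focal population. With a
#' dead zone of half-width `tol` around zero:
#' both coefficients above `tol` is `competition`; both below `-tol` is
#' `mutualism`; suppression of S only (`alpha_SR > tol`, `alpha_RS` at
#' or below the dead zone) is `sensitive_antagonism`; the mirror case
#' is `resistant_antagonism`; both inside the dead zone is `neutral`.
#'
#' @param alpha_SR Competitive effect of R on S.
#' @param alpha_RS Competitive effect of S on R.
#' @param tol Dead-zone half-width (>= 0), default 0.05.
#' @return One of `"mutualism"`, `"competition"`,
#'   `"sensitive_antagonism"`, `"resistant_antagonism"`, `"neutral"`.
#' @export
classify_interaction <- function(alpha_SR, alpha_RS, tol = 0.05) {
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  if (alpha_SR > tol && alpha_RS > tol) return("competition")
  if (alpha_SR < -tol && alpha_RS < -tol) return("mutualism")
  if (alpha_SR > tol) return("sensitive_antagonism")
  if (alpha_RS > tol) return("resistant_antagonism")
  "neutral"
}

#' Double-bind report from a fit summary
#'
#' For every condition in the summary: the double-bind score, the cost
#' of resistance and the competition classification, all computed from
#' the across-replicate parameter means. When the per-replicate fit
#' results are supplied the score's across-replicate dispersion (SEM)
#' is reported as well, rather than relying on parameter means alone. A
#' double bind is flagged when the score is positive in an NK-containing
#' condition.
#'
#' @param summary An `nk_fit_summary` from [summarize_fits()].
#' @param results Optional [staged_fit()] output for per-replicate score
#'   dispersion.
#' @param tol Dead zone for [classify_interaction()].
#' @return An object of class `nk_report`: a data frame with columns
#'   `condition`, `double_bind_score`, `score_sem`, `cost_of_resistance`,
#'   `interaction_class`, `double_bind`, plus an `applicable` attribute
#'   that is `FALSE` when no NK-containing condition is present.
#' @export
analyze_summary <- function(summary, results = NULL, tol = 0.05) {
  stopifnot(inherits(summary, "nk_fit_summary"))
  conds <- unique(summary$condition)
  rows <- lapply(conds, function(cond) {
    p <- summary_params(summary, cond)
    nk_cond <- cond %in% c("NK", "RTNK")
    score <- if (nk_cond) p$lambda_RN - p$lambda_SN else NA_real_
    score_sem <- NA_real_
    if (nk_cond && !is.null(results) && !is.null(results[[cond]])) {
      ok <- Filter(function(f) f$converged, results[[cond]])
      per_rep <- vapply(ok, function(f) f$params$lambda_RN -
                          f$params$lambda_SN, 0)
      if (length(per_rep) > 1L)
        score_sem <- stats::sd(per_rep) / sqrt(length(per_rep))
    }
    data.frame(
      condition = cond,
      double_bind_score = score,
      score_sem = score_sem,
      cost_of_resistance = cost_of_resistance(p),
      interaction_class = classify_interaction(p$alpha_SR, p$alpha_RS, tol),
      double_bind = nk_cond && isTRUE(score > 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "applicable") <- any(conds %in% c("NK", "RTNK"))
  class(out) <- c("nk_report", "data.frame")
  out
}

#' @export
print.nk_report <- function(x, ...) {
  if (!isTRUE(attr(x, "applicable"))) {
    cat("Double-bind analysis: not applicable (no NK-containing condition)\n")
  } else {
    cat("Double-bind analysis (score = lambda_RN - lambda_SN, /unit N/h)\n")
  }
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
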