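# Parameter containers and serialization for the three-population model.

#' Names of the full-model parameters
#'
#' The full model tracks radiation-sensitive tumour cells (S),
#' radiation-resistant tumour cells (R) and natural-killer cells (N).
#' Its ten parameters are the intrinsic growth rates `r_S`, `r_R`, `r_N`
#' (per hour), the carrying capacities `K_S`, `K_R`, `K_N` (units of
#' 1e5 cells), the competition coefficients `alpha_SR` (effect of R on S)
#' and `alpha_RS` (effect of S on R), and the NK kill rates `lambda_SN`,
#' `lambda_RN` (per unit N per hour, first index = target).
#'
#' @return Character vector of the ten parameter names, in canonical order.
#' @export
lv_param_names <- function() {
  c("r_S", "r_R", "r_N", "K_S", "K_R", "K_N",
    "alpha_SR", "alpha_RS", "lambda_SN", "lambda_RN")
}

#' Treatment conditions
#'
#' The four arms of the co-culture design: untreated (`UT`), radiation
#' only (`RT`), NK cells only (`NK`) and the combination (`RTNK`).
#'
#' @return Character vector of condition codes.
#' @export
lv_conditions <- function() c("UT", "RT", "NK", "RTNK")

#' Construct a full-model parameter set
#'
#' Bundles the ten Lotka-Volterra parameters with a per-parameter
#' fixed/free mask used by the fitting machinery. Growth rates must lie
#' in \[0, 1\] per hour, carrying capacities in (0, 10\] (units of 1e5
#' cells), and the interaction coefficients (alphas and lambdas) in
#' \[-15, 15\].
#'
#' @param r_S,r_R,r_N Intrinsic growth rates, per hour.
#' @param K_S,K_R,K_N Carrying capacities, units of 1e5 cells.
#' @param alpha_SR Competitive effect of R on S (dimensionless).
#' @param alpha_RS Competitive effect of S on R (dimensionless).
#' @param lambda_SN,lambda_RN NK kill rates on S and R, per (unit N * hour).
#' @param fixed Character vector of parameter names held constant during
#'   fitting.
#' @return An object of class `lv_params`: a named list of the ten values
#'   plus the `fixed` mask.
#' @examples
#' p <- parameter_set(r_S = 0.032, r_R = 0.0357, K_S = 1.27, K_R = 0.779,
#'                    alpha_SR = 1.54, alpha_RS = 0.3)
#' p$r_S
#' @export
parameter_set <- function(r_S = 0, r_R = 0, r_N = 0,
                          K_S = 1, K_R = 1, K_N = 1,
                          alpha_SR = 0, alpha_RS = 0,
                          lambda_SN = 0, lambda_RN = 0,
                          fixed = character()) {
  p <- list(r_S = r_S, r_R = r_R, r_N = r_N,
            K_S = K_S, K_R = K_R, K_N = K_N,
            alpha_SR = alpha_SR, alpha_RS = alpha_RS,
            lambda_SN = lambda_SN, lambda_RN = lambda_RN,
            fixed = as.character(fixed))
  class(p) <- "lv_params"
  validate_parameter_set(p)
  p
}

validate_parameter_set <- function(p) {
  stopifnot(inherits(p, "lv_params"))
  num <- vapply(p[lv_param_names()], function(x) {
    is.numeric(x) && length(x) == 1L && is.finite(x)
  }, logical(1))
  if (!all(num)) {
    stop("all parameters must be finite scalars; offending: ",
         paste(lv_param_names()[!num], collapse = ", "), call. = FALSE)
  }
  for (nm in c("r_S", "r_R", "r_N")) {
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must lie in [0, 1] per hour, got ", p[[nm]], call. = FALSE)
  }
  for (nm in c("K_S", "K_R", "K_N")) {
    if (p[[nm]] <= 0 || p[[nm]] > 10)
      stop(nm, " must lie in (0, 10] (1e5 cells), got ", p[[nm]], call. = FALSE)
  }
  for (nm in c("alpha_SR", "alpha_RS", "lambda_SN", "lambda_RN")) {
    if (p[[nm]] < -15 || p[[nm]] > 15)
      stop(nm, " must lie in [-15, 15], got ", p[[nm]], call. = FALSE)
  }
  bad <- setdiff(p$fixed, lv_param_names())
  if (length(bad))
    stop("unknown parameter name(s) in fixed mask: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(p)
}

#' @export
print.lv_params <- function(x, ...) {
  cat("Lotka-Volterra parameter set (rates /h, K in 1e5 cells)\n")
  for (nm in lv_param_names()) {
    cat(sprintf("  %-10s %10.5g%s\n", nm, x[[nm]],
                if (nm %in% x$fixed) "  (fixed)" else ""))
  }
  invisible(x)
}

#' Update parameter values
#'
#' @param p An `lv_params` object.
#' @param values Named numeric vector or list of replacement values.
#' @return The updated, re-validated `lv_params` object.
#' @export
update_params <- function(p, values) {
  stopifnot(inherits(p, "lv_params"))
  values <- as.list(values)
  bad <- setdiff(names(values), lv_param_names())
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(values)) p[[nm]] <- unname(values[[nm]])
  validate_parameter_set(p)
  p
}

#' Serialize a parameter set to JSON
#'
#' One key per parameter symbol plus a `"fixed"` array; the inverse of
#' [params_from_json()]. Round-tripping is lossless (full double
#' precision is written).
#'
#' @param p An `lv_params` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
params_to_json <- function(p, path = NULL) {
  validate_parameter_set(p)
  doc <- c(p[lv_param_names()], list(fixed = I(p$fixed)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Deserialize a parameter set from JSON
#'
#' @param x JSON string or path to a JSON file written by
#'   [params_to_json()].
#' @return An `lv_params` object.
#' @export
params_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  miss <- setdiff(lv_param_names(), names(doc))
  if (length(miss))
    stop("JSON document missing parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  do.call(parameter_set, c(lapply(doc[lv_param_names()], as.numeric),
                           list(fixed = as.character(doc$fixed))))
}

#' Check a parameter set against a treatment condition
#'
#' No-NK arms (`UT`, `RT`) must carry `lambda_SN = lambda_RN = 0` and
#' `r_N = 0`: NK cells are absent so their growth and kill terms are
#' structurally zero.
#'
#' @param condition One of [lv_conditions()].
#' @param p An `lv_params` object.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_condition_params <- function(condition, p) {
  condition <- match.arg(condition, lv_conditions())
  validate_parameter_set(p)
  if (condition %in% c("UT", "RT")) {
    if (p$lambda_SN != 0 || p$lambda_RN != 0 || p$r_N != 0)
      stop("condition ", condition,
           " requires lambda_SN = lambda_RN = 0 and r_N = 0", call. = FALSE)
  }
  invisible(TRUE)
}
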