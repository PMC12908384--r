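# Packaged reference parameter estimates for the four treatment arms.

#' Reference fitted parameters for the co-culture assay
#'
#' Loads the packaged across-replicate mean parameter estimates for the
#' four treatment arms (UT, RT, NK, RTNK) of the radiation /
#' NK-cell co-culture experiment, with fixed flags marking parameters
#' frozen during the staged fit (the no-NK arms carry structural zeros;
#' treated arms carry the untreated carrying capacities `K_S = 1.27`,
#' `K_R = 0.779`, and `K_N = 1` is always fixed). These values serve as
#' ground truth for the synthetic generator and as the benchmark for
#' self-consistency recovery.
#'
#' @param path Optional path to an alternative JSON fixture with the
#'   same layout.
#' @return Named list mapping each condition to an `lv_params` object.
#' @examples
#' truth <- reference_params()
#' truth$NK$lambda_RN - truth$NK$lambda_SN  # > 0: the double bind
#' @export
reference_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_params.json",
                        package = "nkbind", mustWork = TRUE)
  doc <- jsonlite::fromJSON(path)
  doc$comment <- NULL
  miss <- setdiff(lv_conditions(), names(doc))
  if (length(miss))
    stop("fixture corrupted: missing condition(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(lv_conditions(), function(cond) {
    entry <- doc[[cond]]
    p <- tryCatch(
      do.call(parameter_set,
              c(entry[lv_param_names()],
                list(fixed = as.character(entry$fixed)))),
      error = function(e) stop("fixture corrupted for condition ", cond,
                               ": ", conditionMessage(e), call. = FALSE))
    check_condition_params(cond, p)
    p
  })
  names(out) <- lv_conditions()
  out
}
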