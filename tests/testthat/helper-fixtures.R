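# Shared fixtures: all data are generated in code at test time.

# Compact design for fitting tests: three fractions, hourly-coarse grid.
small_design <- function(conditions = c("UT", "NK"), n_replicates = 2) {
  experiment_design(fractions = c(0, 0.5, 1), n_replicates = n_replicates,
                    sample_interval = 12, horizon = 144,
                    conditions = conditions)
}

# A mean/SEM summary built directly from the packaged reference
# parameter means (SEM = 0), as if every replicate had hit the mean.
fixture_summary <- function(truth = reference_params(), n = 12) {
  rows <- list()
  for (cond in names(truth)) {
    p <- truth[[cond]]
    for (nm in lv_param_names()) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, parameter = nm, mean = p[[nm]], sem = 0,
        n = n, fixed = nm %in% p$fixed)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nk_fit_summary", "data.frame")
  out
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), rel_tol)
}
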