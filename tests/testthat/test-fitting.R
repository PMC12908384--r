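# Staged bounded least-squares inference.

truth <- reference_params()

test_that("residuals vanish at the generating truth and count correctly", {
  d <- experiment_design(n_replicates = 1, conditions = "UT")
  ds <- generate_dataset(truth, d, noise_model("none"))
  slice <- ds[ds$condition == "UT" & ds$replicate == 1, ]
  r <- lv_residuals(truth$UT, slice, d)
  expect_length(r, 7 * 26 * 2)  # fractions x times x channels = 364
  expect_equal(max(abs(r)), 0)
  # perturbing a parameter off the truth must cost something
  perturbed <- update_params(truth$UT, c(r_S = truth$UT$r_S * 1.1))
  expect_gt(sum(lv_residuals(perturbed, slice, d)^2), 0)
})

test_that("a noiseless untreated replicate is recovered within 1%", {
  d <- experiment_design(n_replicates = 1, conditions = "UT")
  ds <- generate_dataset(truth, d, noise_model("none"))
  slice <- ds[ds$condition == "UT" & ds$replicate == 1, ]
  fit <- fit_replicate(slice, "UT", fit_config(n_multistart = 1), d)
  expect_true(fit$converged)
  for (nm in fit$free)
    expect_rel_equal(fit$params[[nm]], truth$UT[[nm]], 0.01)
  # structural zeros of the no-NK arm are held fixed
  expect_equal(fit$params$lambda_SN, 0)
  expect_equal(fit$params$lambda_RN, 0)
  expect_equal(fit$params$r_N, 0)
  expect_true(all(c("r_N", "lambda_SN", "lambda_RN", "K_N") %in%
                    fit$params$fixed))
  # no estimate exits its bounds
  expect_true(all(!fit$at_bounds))
})

test_that("multistart never worsens the noiseless best loss", {
  d <- experiment_design(fractions = c(0, 0.5, 1), n_replicates = 1,
                         sample_interval = 12, horizon = 144,
                         conditions = "UT")
  ds <- generate_dataset(truth, d, noise_model("none"))
  slice <- ds[ds$condition == "UT" & ds$replicate == 1, ]
  f1 <- fit_replicate(slice, "UT", fit_config(n_multistart = 1, seed = 5), d)
  f4 <- fit_replicate(slice, "UT", fit_config(n_multistart = 4, seed = 5), d)
  expect_lte(f4$loss, f1$loss + 1e-12)
  expect_equal(f1$loss, f4$loss, tolerance = 1e-6)
})

test_that("the staged fit freezes treated capacities at the untreated means", {
  d <- small_design(conditions = c("UT", "RT", "NK"), n_replicates = 2)
  ds <- generate_dataset(truth, d, noise_model("none"))
  res <- staged_fit(ds, fit_config(n_multistart = 1), d)
  expect_named(res, c("UT", "RT", "NK"))
  expect_length(res$RT, 2)
  K_S_bar <- mean(vapply(res$UT, function(f) f$params$K_S, 0))
  K_R_bar <- mean(vapply(res$UT, function(f) f$params$K_R, 0))
  for (cond in c("RT", "NK")) {
    for (f in res[[cond]]) {
      expect_equal(f$params$K_S, K_S_bar)
      expect_equal(f$params$K_R, K_R_bar)
      expect_true(all(c("K_S", "K_R", "K_N") %in% f$params$fixed))
      expect_equal(f$params$K_N, 1)
    }
  }
  # NK arm frees the NK growth and kill rates and recovers them
  for (f in res$NK) {
    expect_true(all(c("r_N", "lambda_SN", "lambda_RN") %in% f$free))
    expect_rel_equal(f$params$lambda_RN, truth$NK$lambda_RN, 0.05)
  }
})

test_that("staged fitting requires the untreated condition", {
  d <- small_design(conditions = "NK", n_replicates = 1)
  ds <- generate_dataset(truth["NK"], d, noise_model("none"))
  expect_error(staged_fit(ds, fit_config(n_multistart = 1), d),
               "untreated")
})

test_that("a UT-only dataset yields a single-condition result map", {
  d <- small_design(conditions = "UT", n_replicates = 1)
  ds <- generate_dataset(truth, d, noise_model("none"))
  res <- staged_fit(ds, fit_config(n_multistart = 1), d)
  expect_named(res, "UT")
})

test_that("summaries compute mean and SEM across replicates", {
  d <- small_design(conditions = "UT", n_replicates = 2)
  ds <- generate_dataset(truth, d, noise_model("none"))
  res <- staged_fit(ds, fit_config(n_multistart = 1), d)
  # hand the summary two synthetic replicates with known spread
  res$UT[[1]]$params <- update_params(res$UT[[1]]$params, c(r_S = 0.03))
  res$UT[[2]]$params <- update_params(res$UT[[2]]$params, c(r_S = 0.04))
  s <- summarize_fits(res)
  row <- s[s$condition == "UT" & s$parameter == "r_S", ]
  expect_equal(row$mean, 0.035)
  expect_equal(row$sem, sd(c(0.03, 0.04)) / sqrt(2))
  expect_equal(row$sem, 0.005)
  expect_equal(row$n, 2)
  kn <- s[s$condition == "UT" & s$parameter == "K_N", ]
  expect_true(kn$fixed)
  expect_equal(kn$mean, 1)
  expect_equal(kn$sem, 0)
  expect_error(summarize_fits(list()), "empty")
})

test_that("identical replicates give zero SEM throughout", {
  d <- small_design(conditions = "UT", n_replicates = 2)
  ds <- generate_dataset(truth, d, noise_model("none"))
  res <- staged_fit(ds, fit_config(n_multistart = 1), d)
  s <- summarize_fits(res)
  expect_true(all(s$sem < 1e-6))
})

test_that("estimates never exit their configured bounds (noisy data)", {
  d <- small_design(conditions = "UT", n_replicates = 2)
  ds <- generate_dataset(truth, d, noise_model(cv = 0.3, seed = 21))
  res <- staged_fit(ds, fit_config(n_multistart = 2, seed = 2), d)
  for (f in res$UT) {
    p <- f$params
    expect_true(all(c(p$r_S, p$r_R, p$r_N) >= 0 &
                      c(p$r_S, p$r_R, p$r_N) <= 1))
    expect_true(all(c(p$K_S, p$K_R) > 0 & c(p$K_S, p$K_R) <= 10))
    expect_true(all(abs(c(p$alpha_SR, p$alpha_RS)) <= 15))
  }
})

test_that("hold-out validation is near-zero on noiseless data and errors on degenerate splits", {
  d <- small_design(conditions = "UT", n_replicates = 2)
  ds <- generate_dataset(truth, d, noise_model("none"))
  hv <- holdout_validate(ds, split = 0.5, config = fit_config(n_multistart = 1),
                         design = d)
  expect_equal(hv$n_train, 1)
  expect_equal(hv$n_validation, 1)
  expect_lt(hv$validation_loss, 1e-10)
  expect_error(holdout_validate(ds, split = c(1, 2),
                                config = fit_config(n_multistart = 1),
                                design = d),
               "degenerate")
})

test_that("hold-out validation loss is comparable to training loss under noise", {
  d <- small_design(conditions = "UT", n_replicates = 4)
  ds <- generate_dataset(truth, d, noise_model(cv = 0.1, seed = 13))
  hv <- holdout_validate(ds, split = 0.5, config = fit_config(n_multistart = 1),
                         design = d)
  expect_lt(hv$validation_loss, 3 * hv$train_loss)
})
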