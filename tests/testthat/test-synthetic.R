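# Synthetic co-culture generator and CSV round trips.

test_that("the default design matches the co-culture assay layout", {
  d <- default_design()
  expect_equal(d$fractions, c(0, 0.1, 0.25, 0.50, 0.75, 0.9, 1))
  expect_equal(d$n_replicates, 12L)
  expect_equal(design_times(d), seq(0, 150, 6))
  expect_length(design_times(d), 26)
  expect_equal(d$tumor_seed, 2000)
  expect_equal(d$et_ratio, 5)
  expect_equal(d$conditions, c("UT", "RT", "NK", "RTNK"))
})

test_that("design invariants are enforced", {
  expect_error(experiment_design(fractions = c(0.5, 0.1)), "sorted")
  expect_error(experiment_design(fractions = c(0, 1.5)), "0, 1")
  expect_error(experiment_design(sample_interval = 0), "sample_interval")
  expect_error(experiment_design(horizon = 2), "horizon")
  expect_error(experiment_design(tumor_seed = 0), "tumor_seed")
})

test_that("a noiseless dataset reproduces the forward simulation exactly", {
  truth <- reference_params()
  d <- experiment_design(n_replicates = 1, conditions = c("UT", "NK"))
  ds <- generate_dataset(truth, d, noise_model("none"))
  # 2 conditions x 7 fractions x 1 replicate x 26 times
  expect_equal(nrow(ds), 2 * 7 * 26)
  for (f in c(0, 0.5, 1)) {
    sub <- ds[ds$condition == "NK" & ds$f == f, ]
    init <- c(S = 2000 * (1 - f) / 1e5, R = 2000 * f / 1e5, N = 0.1)
    tr <- simulate_lv(truth$NK, init, design_times(d))
    # stacked multi-well integration vs a single-well solve: agreement
    # is to solver tolerance, not bitwise
    expect_equal(sub$count_S, tr$S, tolerance = 1e-7)
    expect_equal(sub$count_R, tr$R, tolerance = 1e-7)
  }
})

test_that("the full default design yields the expected row count", {
  truth <- reference_params()
  ds <- generate_dataset(truth, default_design(), noise_model("none"))
  expect_equal(nrow(ds), 4 * 7 * 12 * 26)  # 8736
})

test_that("monoculture wells stay pure", {
  truth <- reference_params()
  d <- experiment_design(n_replicates = 2, conditions = "UT")
  ds <- generate_dataset(truth, d, noise_model(cv = 0.2, seed = 3))
  expect_true(all(ds$count_R[ds$f == 0] == 0))
  expect_true(all(ds$count_S[ds$f == 1] == 0))
})

test_that("the lognormal noise law delivers the configured CV", {
  truth <- reference_params()
  d <- experiment_design(fractions = 0.5, n_replicates = 1000,
                         sample_interval = 6, horizon = 6,
                         conditions = "UT")
  clean <- generate_dataset(truth, d, noise_model("none"))
  noisy <- generate_dataset(truth, d, noise_model(cv = 0.1, seed = 11))
  pick <- noisy$time_h == 6
  ratio <- noisy$count_S[pick] / clean$count_S[pick]
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  cv_hat <- sd(ratio) / mean(ratio)
  expect_gt(cv_hat, 0.09)
  expect_lt(cv_hat, 0.11)
})

test_that("datasets are byte-identical given the same seed", {
  truth <- reference_params()
  d <- experiment_design(n_replicates = 2, conditions = c("UT", "NK"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(generate_dataset(truth, d, noise_model(cv = 0.1,
                                                           seed = 9)), f1)
  write_dataset_csv(generate_dataset(truth, d, noise_model(cv = 0.1,
                                                           seed = 9)), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(generate_dataset(truth, d, noise_model(cv = 0.1,
                                                           seed = 10)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("CSV write/read is the identity on records and provenance", {
  truth <- reference_params()
  d <- experiment_design(fractions = c(0, 1), n_replicates = 1,
                         sample_interval = 75, horizon = 150,
                         conditions = "UT")
  ds <- generate_dataset(truth, d, noise_model(cv = 0.05, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  for (col in c("condition", "replicate", "f", "time_h"))
    expect_equal(back[[col]], ds[[col]])
  expect_equal(back$count_S, ds$count_S, tolerance = 1e-15)
  expect_equal(back$count_R, ds$count_R, tolerance = 1e-15)
  prov <- attr(back, "provenance")
  expect_equal(prov$noise$seed, 4)
  expect_equal(prov$truth$UT$r_S, truth$UT$r_S)
  expect_equal(unlist(prov$design$fractions), c(0, 1))
})

test_that("malformed CSV inputs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("condition,replicate,f,time_h,count_S",
               "UT,1,0,0,0.02"), path)
  expect_error(read_dataset_csv(path), "count_R")

  writeLines(c("condition,replicate,f,time_h,count_S,count_R",
               "UT,1,0,0,0.02,-0.5"), path)
  expect_error(read_dataset_csv(path), "negative count at row 1")

  writeLines(c("condition,replicate,f,time_h,count_S,count_R",
               "UT,1,0,0,0.02,0",
               "UT,1,0,6,0.02,0",
               "UT,1,1,0,0,0.02"), path)
  expect_error(read_dataset_csv(path), "ragged")
})

test_that("missing truth conditions are a configuration error", {
  truth <- reference_params()["UT"]
  d <- experiment_design(n_replicates = 1, conditions = c("UT", "NK"))
  expect_error(generate_dataset(truth, d, noise_model("none")),
               "missing condition")
})
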