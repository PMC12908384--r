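# Synthetic co-culture generator emulating the IncuCyte competition assay:
# two fluorescently labelled tumour lines seeded across a range of initial
# resistant fractions, with or without NK effectors, imaged on a fixed
# cadence. Counts are stored in 1e5-cell units to match the fitted
# carrying-capacity scale.

#' Construct a co-culture experiment design
#'
#' @param fractions Initial resistant fractions f, in \[0, 1\], sorted,
#'   unique.
#' @param n_replicates Number of replicate wells per fraction.
#' @param sample_interval Imaging cadence, hours.
#' @param horizon Total duration, hours.
#' @param tumor_seed Tumour cells seeded per well (raw cells).
#' @param et_ratio NK effector:target seeding ratio.
#' @param conditions Subset of [lv_conditions()] present in the run.
#' @return An object of class `nk_design`.
#' @export
experiment_design <- function(fractions = c(0, 0.1, 0.25, 0.50, 0.75, 0.9, 1),
                              n_replicates = 12,
                              sample_interval = 6,
                              horizon = 150,
                              tumor_seed = 2000,
                              et_ratio = 5,
                              conditions = lv_conditions()) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(fractions, strictly = TRUE))
    stop("fractions must be sorted and unique", call. = FALSE)
  if (sample_interval <= 0) stop("sample_interval must be > 0", call. = FALSE)
  if (horizon < sample_interval)
    stop("horizon must be >= sample_interval", call. = FALSE)
  if (tumor_seed <= 0) stop("tumor_seed must be > 0", call. = FALSE)
  conditions <- match.arg(conditions, lv_conditions(), several.ok = TRUE)
  d <- list(fractions = fractions, n_replicates = as.integer(n_replicates),
            sample_interval = sample_interval, horizon = horizon,
            tumor_seed = tumor_seed, et_ratio = et_ratio,
            conditions = conditions)
  class(d) <- "nk_design"
  d
}

#' The default co-culture design
#'
#' Seven seeding fractions f = 0, 0.1, 0.25, 0.5, 0.75, 0.9, 1; 12
#' replicates; imaging every 6 h for 150 h (26 time points); 2000 tumour
#' cells seeded per well; NK effectors at a 5:1 effector:target ratio;
#' all four treatment arms.
#'
#' @return An `nk_design` object.
#' @export
default_design <- function() experiment_design()

#' Sampling times of a design
#'
#' @param design An `nk_design` object.
#' @return Numeric vector `0, dt, ..., <= horizon` (hours).
#' @export
design_times <- function(design) {
  seq(0, design$horizon, by = design$sample_interval)
}

# Initial state (1e5-cell units) for one well of a design.
design_init <- function(design, f, condition) {
  scale <- 1e5
  list(S = design$tumor_seed * (1 - f) / scale,
       R = design$tumor_seed * f / scale,
       N = if (condition %in% c("NK", "RTNK"))
         design$et_ratio * design$tumor_seed / scale else 0)
}

#' Construct an observation-noise model
#'
#' Imaging-derived counts carry roughly proportional error and cannot go
#' negative, so the default law is multiplicative lognormal, mean-one,
#' with a given coefficient of variation applied independently per
#' observation. `law = "none"` reproduces the noiseless simulation
#' exactly.
#'
#' @param law `"none"` or `"lognormal_multiplicative"`.
#' @param cv Coefficient of variation (>= 0) of the multiplicative
#'   factor.
#' @param seed RNG seed making the generated dataset reproducible.
#' @return An object of class `nk_noise`.
#' @export
noise_model <- function(law = c("lognormal_multiplicative", "none"),
                        cv = 0.10, seed = 1L) {
  law <- match.arg(law)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  n <- list(law = law, cv = cv, seed = as.integer(seed))
  class(n) <- "nk_noise"
  n
}

# Mean-one lognormal factors with coefficient of variation cv.
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -sigma2 / 2, sd = sqrt(sigma2)))
}

#' Generate a synthetic co-culture dataset
#'
#' Simulates every (condition, fraction) well of the design from the
#' given ground-truth parameters, samples S and R on the design's time
#' grid, and perturbs the counts by the observation-noise law. Initial
#' conditions follow the seeding: `S(0) = tumor_seed * (1 - f)`,
#' `R(0) = tumor_seed * f` (converted to 1e5-cell units), and for
#' NK-containing arms `N(0) = et_ratio * tumor_seed`. NK counts are
#' never observed.
#'
#' @param truth Named list mapping each condition in `design$conditions`
#'   to its `lv_params` ground truth. No-NK conditions must carry zero
#'   NK parameters.
#' @param design An `nk_design` object.
#' @param noise An `nk_noise` object.
#' @return A data frame of class `nk_dataset` with columns `condition`,
#'   `replicate`, `f`, `time_h`, `count_S`, `count_R` (counts in 1e5
#'   cells) and a `provenance` attribute recording truth, design, noise
#'   and seed.
#' @export
generate_dataset <- function(truth, design = default_design(),
                             noise = noise_model()) {
  stopifnot(inherits(design, "nk_design"), inherits(noise, "nk_noise"))
  miss <- setdiff(design$conditions, names(truth))
  if (length(miss))
    stop("truth missing condition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cond in design$conditions) check_condition_params(cond, truth[[cond]])

  times <- design_times(design)
  nt <- length(times)
  nf <- length(design$fractions)

  # one noiseless stacked solve per condition, reused across replicates
  clean <- lapply(design$conditions, function(cond) {
    inits <- t(vapply(design$fractions, function(f) {
      ic <- design_init(design, f, cond)
      c(ic$S, ic$R)
    }, numeric(2)))
    N0 <- design_init(design, design$fractions[1L], cond)$N
    simulate_wells(truth[[cond]], inits, N0, times)
  })
  names(clean) <- design$conditions

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(noise$seed)

  rows <- vector("list", length(design$conditions) * design$n_replicates)
  k <- 0L
  for (cond in design$conditions) {
    sim <- clean[[cond]]
    S <- as.vector(sim$S)  # time-major within fraction blocks
    R <- as.vector(sim$R)
    for (rep_id in seq_len(design$n_replicates)) {
      if (noise$law == "none") {
        cs <- S; cr <- R
      } else {
        cs <- S * lognormal_factors(length(S), noise$cv)
        cr <- R * lognormal_factors(length(R), noise$cv)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        condition = cond,
        replicate = rep_id,
        f = rep(design$fractions, each = nt),
        time_h = rep(times, nf),
        count_S = cs,
        count_R = cr)
    }
  }
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  attr(ds, "provenance") <- list(
    truth = lapply(truth[design$conditions], function(p)
      c(p[lv_param_names()], list(fixed = p$fixed))),
    design = unclass(design),
    noise = unclass(noise))
  class(ds) <- c("nk_dataset", "data.frame")
  ds
}

dataset_columns <- c("condition", "replicate", "f", "time_h",
                     "count_S", "count_R")

#' Write a dataset to tidy CSV (with a provenance sidecar)
#'
#' Schema: `condition,replicate,f,time_h,count_S,count_R`, UTF-8, "."
#' decimal separator. Provenance (ground truth, design, noise, seed) is
#' written to `<path>.json`.
#'
#' @param dataset An `nk_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(all(dataset_columns %in% names(dataset)))
  df <- as.data.frame(dataset)[, dataset_columns]
  for (col in c("f", "time_h", "count_S", "count_R"))
    df[[col]] <- vapply(df[[col]], function(x) sprintf("%.17g", x), "")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  prov <- attr(dataset, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a dataset from tidy CSV
#'
#' Validates the header, nonnegativity of counts, and that every
#' (condition, replicate, fraction) series shares the same time grid;
#' the provenance sidecar `<path>.json` is restored when present.
#'
#' @param path CSV path written by [write_dataset_csv()].
#' @return An `nk_dataset`.
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(dataset_columns, names(df))
  if (length(miss))
    stop("malformed dataset CSV: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, dataset_columns]
  bad <- which(df$count_S < 0 | df$count_R < 0)
  if (length(bad))
    stop("negative count at row ", bad[1L], call. = FALSE)
  grids <- split(df$time_h,
                 interaction(df$condition, df$replicate, df$f, drop = TRUE))
  ref <- grids[[1L]]
  for (g in names(grids)) {
    if (!identical(length(grids[[g]]), length(ref)) ||
        any(grids[[g]] != ref)) {
      off <- which(interaction(df$condition, df$replicate, df$f,
                               drop = TRUE) == g)[1L]
      stop("ragged time grid in series ", g, " (first row ", off, ")",
           call. = FALSE)
    }
  }
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(df, "provenance") <- jsonlite::fromJSON(side,
                                                 simplifyDataFrame = FALSE)
  class(df) <- c("nk_dataset", "data.frame")
  df
}
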