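# Pipeline driver tying the stages together: generate -> fit ->
# summarize -> analyze, plus simulate and sweep. A thin command-line
# wrapper lives in inst/scripts/nkbind.

pipeline_subcommands <- c("generate", "simulate", "fit", "summarize",
                          "analyze", "sweep")

config_keys <- list(
  generate = c("subcommand", "out", "truth", "design", "noise", "seed"),
  simulate = c("subcommand", "out", "params", "init", "times", "seed"),
  fit = c("subcommand", "data", "out", "fit", "seed"),
  summarize = c("subcommand", "data", "out", "fit", "seed"),
  analyze = c("subcommand", "data", "out", "fit", "seed", "tol"),
  sweep = c("subcommand", "out", "mode", "reduced", "grid", "horizon",
            "seed"))

config_digest <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small stable digest without extra dependencies
  sprintf("%08x", sum(utf8ToInt(as.character(json)) *
                        (seq_len(nchar(json)) %% 251 + 1)) %% .Machine$integer.max)
}

write_provenance <- function(path, config) {
  jsonlite::write_json(
    list(package = "nkbind",
         version = as.character(utils::packageVersion("nkbind")),
         seed = config$seed %||% NA,
         config_digest = config_digest(config),
         config = config),
    paste0(path, ".provenance.json"), auto_unbox = TRUE, digits = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_design <- function(overrides) {
  do.call(experiment_design, overrides %||% list())
}

build_truth <- function(spec) {
  if (is.null(spec) || identical(spec, "reference")) return(reference_params())
  if (is.character(spec)) return(reference_params(path = spec))
  stop("truth must be \"reference\" or a path to a parameter JSON",
       call. = FALSE)
}

#' Run one pipeline stage
#'
#' Drives the package end-to-end from a single configuration list (the
#' same structure the `nkbind` command-line script assembles from its
#' flags). Stages: `generate` (synthetic dataset CSV), `simulate`
#' (trajectory CSV), `fit` (staged fit; writes per-replicate results and
#' the mean/SEM summary), `summarize` (summary only), `analyze`
#' (double-bind report JSON) and `sweep` (reduced-model sweep CSV).
#' Every artifact gets a `.provenance.json` sidecar recording package
#' version, seed and a digest of the configuration. Outputs are a pure
#' function of (config, seed, packaged fixture).
#'
#' @param config Named list with at least `subcommand` and `out`;
#'   remaining keys depend on the stage (see the command-line help).
#'   Unknown keys are rejected.
#' @return Invisibly, the path(s) of the artifacts written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  sub <- config$subcommand
  if (is.null(sub) || !sub %in% pipeline_subcommands)
    stop("unknown subcommand: ", sub %||% "<missing>",
         "; expected one of ", paste(pipeline_subcommands, collapse = "|"),
         call. = FALSE)
  unknown <- setdiff(names(config), config_keys[[sub]])
  if (length(unknown))
    stop("unknown config key(s) for ", sub, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(config$out)) stop("config$out is required", call. = FALSE)
  out <- config$out
  seed <- as.integer(config$seed %||% 1L)

  ok <- FALSE
  on.exit(if (!ok) unlink(c(out, paste0(out, c(".json", ".provenance.json")))))

  if (sub == "generate") {
    truth <- build_truth(config$truth)
    design <- build_design(config$design)
    noise_args <- config$noise %||% list()
    noise_args$seed <- seed
    noise <- do.call(noise_model, noise_args)
    ds <- generate_dataset(truth, design, noise)
    write_dataset_csv(ds, out)
  } else if (sub == "simulate") {
    p <- params_from_json(config$params)
    init <- unlist(config$init %||% list(S = 0.01, R = 0.01, N = 0))
    times <- config$times %||% seq(0, 150, by = 6)
    if (length(times) == 3L && is.null(names(times)) && !is.null(config$times))
      times <- seq(times[1], times[2], by = times[3])
    write_trajectory_csv(simulate_lv(p, init, times), out)
  } else if (sub %in% c("fit", "summarize", "analyze")) {
    ds <- read_dataset_csv(config$data)
    fit_args <- config$fit %||% list()
    fit_args$seed <- seed
    cfg <- do.call(fit_config, fit_args)
    results <- staged_fit(ds, cfg)
    summ <- summarize_fits(results)
    if (sub == "analyze") {
      report <- analyze_summary(summ, results,
                                tol = config$tol %||% 0.05)
      jsonlite::write_json(
        list(applicable = attr(report, "applicable"),
             report = as.data.frame(report)),
        out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    } else {
      write_summary_csv(summ, out)
      if (sub == "fit")
        jsonlite::write_json(
          lapply(results, function(fits) lapply(fits, function(f)
            list(condition = f$condition, replicate = f$replicate,
                 estimates = f$params[lv_param_names()],
                 fixed = f$params$fixed, loss = f$loss,
                 converged = f$converged))),
          paste0(out, ".results.json"), auto_unbox = TRUE, digits = NA)
    }
  } else if (sub == "sweep") {
    mode <- match.arg(config$mode, c("delta", "B"))
    red_args <- config$reduced %||% list()
    params <- do.call(reduced_parameter_set, red_args)
    horizon <- config$horizon %||% 500
    sw <- if (mode == "delta") {
      sweep_delta(unlist(config$grid %||% c(0.5, 1, 1.5, 2, 2.5)),
                  params, horizon = horizon)
    } else {
      sweep_B(unlist(config$grid %||% seq(0, 1, by = 0.1)),
              params, horizon = horizon)
    }
    utils::write.csv(sw, out, row.names = FALSE)
  }
  write_provenance(out, config)
  ok <- TRUE
  invisible(out)
}

#' Write a fit summary as CSV
#'
#' Wide layout mirroring the published parameter table: one row per
#' condition, one `mean` and one `sem` column per parameter, with fixed
#' parameters carrying `sem = 0`. The long tidy form is written when
#' `wide = FALSE`.
#'
#' @param summary An `nk_fit_summary`.
#' @param path Output CSV path.
#' @param wide Wide (condition x parameter) or long layout.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path, wide = TRUE) {
  stopifnot(inherits(summary, "nk_fit_summary"))
  if (!wide) {
    utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
    return(invisible(path))
  }
  conds <- unique(summary$condition)
  cols <- lv_param_names()
  wide_df <- data.frame(condition = conds)
  for (nm in cols) {
    sub <- summary[summary$parameter == nm, ]
    sub <- sub[match(conds, sub$condition), ]
    wide_df[[nm]] <- sub$mean
    wide_df[[paste0(nm, "_sem")]] <- sub$sem
  }
  utils::write.csv(wide_df, path, row.names = FALSE)
  invisible(path)
}
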