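# End-to-end orchestration: reconstruct -> train -> optimize ->
# sensitivity -> report. Each stage is a function over a configuration
# and an output directory; stages communicate through plain CSV/JSON
# artifacts so a run is inspectable and reproducible bit-for-bit from
# the configuration alone.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one serializable list. All
#' stage seeds derive from the single `seed`, so one integer reproduces
#' a whole run.
#'
#' @param seed Master seed.
#' @param replicates,noise_scale Dataset reconstruction settings (see
#'   [reconstruct_records()]).
#' @param fraction Training fraction of the split.
#' @param candidates Hidden-layer sizes searched per target.
#' @param lm An [lm_control()].
#' @param nsga An [nsga_config()]; its seed is overridden per
#'   experiment.
#' @param time_bounds `"experiment"` (each sterilant optimized over its
#'   own printed immersion-time range) or `"global"` (the 2.5-15 min
#'   range pooled over all experiments).
#' @param sens_hidden Hidden-layer size used by the sensitivity
#'   analysis.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, replicates = 3, noise_scale = 1,
                            fraction = 0.75,
                            candidates = c(3, 5, 7, 10, 14),
                            lm = lm_control(), nsga = nsga_config(),
                            time_bounds = c("experiment", "global"),
                            sens_hidden = 7) {
  time_bounds <- match.arg(time_bounds)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read and write a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config_json` returns the path invisibly;
#'   `read_config_json` the configuration.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(config_payload(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

config_payload <- function(config) {
  payload <- unclass(config)
  payload$lm <- unclass(payload$lm)
  payload$nsga <- unclass(payload$nsga)
  payload
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    seed = p$seed, replicates = p$replicates, noise_scale = p$noise_scale,
    fraction = p$fraction, candidates = as.numeric(p$candidates),
    lm = do.call(lm_control, p$lm[setdiff(names(p$lm), character(0))]),
    nsga = do.call(nsga_config, p$nsga),
    time_bounds = p$time_bounds, sens_hidden = p$sens_hidden
  )
}

stage_file <- function(outdir, name) file.path(outdir, name)

require_artifact <- function(outdir, name, producer) {
  path <- stage_file(outdir, name)
  if (!file.exists(path)) {
    stop("missing artifact '", name, "'; run ", producer, " first")
  }
  path
}

#' Pipeline stage: reconstruct the replicate-level dataset
#'
#' Writes `records.csv` into `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The records data frame, invisibly.
#' @export
pipeline_reconstruct <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  records <- reconstruct_records(replicates = config$replicates,
                                 noise_scale = config$noise_scale,
                                 seed = derive_seed(config$seed, 1))
  write_records_csv(records, stage_file(outdir, "records.csv"))
  write_config_json(config, stage_file(outdir, "config.json"))
  invisible(records)
}

#' Fit both surrogates on a split
#'
#' Architecture search followed by a final fit, for contamination
#' frequency and explant viability.
#'
#' @param split A `dataset_split`.
#' @param config A [pipeline_config()].
#' @return A list with elements `cf` and `ev` (trained
#'   `mlp_surrogate`s) and `metrics` (the combined [evaluate_mlp()]
#'   table with a `n_hidden` column).
#' @export
fit_surrogates <- function(split, config = pipeline_config()) {
  fits <- lapply(c(cf = "cf", ev = "ev"), function(target) {
    seed_t <- derive_seed(config$seed, if (target == "cf") 11 else 12)
    m <- select_architecture(split$train, target,
                             candidates = config$candidates,
                             seed = seed_t, control = config$lm)
    model <- train_mlp(split$train, target, n_hidden = as.integer(m),
                       seed = seed_t, control = config$lm)
    metrics <- evaluate_mlp(model, split)
    metrics$n_hidden <- as.integer(m)
    list(model = model, metrics = metrics)
  })
  list(
    cf = fits$cf$model,
    ev = fits$ev$model,
    metrics = rbind(fits$cf$metrics, fits$ev$metrics)
  )
}

#' Pipeline stage: train the surrogates
#'
#' Reads `records.csv`, splits it, fits both surrogates and writes
#' `cf_model.json`, `ev_model.json`, `metrics.csv`, `train.csv` and
#' `test.csv`.
#'
#' @inheritParams pipeline_reconstruct
#' @return The fitted surrogate list, invisibly.
#' @export
pipeline_train <- function(config = pipeline_config(), outdir) {
  records <- read_records_csv(
    require_artifact(outdir, "records.csv", "pipeline_reconstruct()")
  )
  split <- split_train_test(records, fraction = config$fraction,
                            seed = derive_seed(config$seed, 2))
  fits <- fit_surrogates(split, config)
  write_mlp_json(fits$cf, stage_file(outdir, "cf_model.json"))
  write_mlp_json(fits$ev, stage_file(outdir, "ev_model.json"))
  utils::write.csv(fits$metrics, stage_file(outdir, "metrics.csv"),
                   row.names = FALSE)
  write_records_csv(split$train, stage_file(outdir, "train.csv"))
  write_records_csv(split$test, stage_file(outdir, "test.csv"))
  invisible(fits)
}

#' Optimize one sterilant's concentration x time domain
#'
#' Runs NSGA-II on the surrogate objectives over the experiment's box
#' constraints and selects the ideal-point compromise member.
#'
#' @param cf_model,ev_model Trained surrogates.
#' @param sterilant One of `sterilants()`.
#' @param config An [nsga_config()].
#' @param time_bounds `"experiment"` or `"global"` (see
#'   [pipeline_config()]).
#' @param refs Ideal-point references, from [compute_refs()].
#' @return A list with `front` (data frame: `experiment`,
#'   `concentration`, `time_min`, `cf_pred`, `ev_pred`, `rank`,
#'   `crowding`), `ideal` (the selected row) and `raw` (the
#'   `pareto_front`).
#' @export
optimize_experiment <- function(cf_model, ev_model, sterilant,
                                config = nsga_config(),
                                time_bounds = c("experiment", "global"),
                                refs = list(cf_ref = 0, ev_ref = 100)) {
  time_bounds <- match.arg(time_bounds)
  sterilant <- match.arg(sterilant, sterilants())
  domain <- experiment_domain(sterilant)
  tb <- if (time_bounds == "experiment") domain$time_bounds
        else global_time_bounds()
  lower <- c(domain$conc_bounds[1], tb[1])
  upper <- c(domain$conc_bounds[2], tb[2])

  objective_fn <- make_objectives(cf_model, ev_model, sterilant)
  res <- nsga2_evolve(objective_fn, lower, upper, config)

  front <- data.frame(
    experiment = sterilant,
    concentration = res$decisions[, 1],
    time_min = res$decisions[, 2],
    cf_pred = res$objectives[, 1],
    ev_pred = -res$objectives[, 2],
    rank = 1L,
    crowding = res$crowding,
    stringsAsFactors = FALSE
  )
  front <- front[order(front$cf_pred), , drop = FALSE]
  rownames(front) <- NULL
  list(front = front, ideal = select_ideal(front, refs), raw = res)
}

#' Pipeline stage: optimize every experiment
#'
#' Reads the trained models and the reconstructed records (for the
#' observed ideal-point references), optimizes each sterilant domain and
#' writes `front_<sterilant>.csv` files plus `ideal_points.csv`.
#'
#' @inheritParams pipeline_reconstruct
#' @param experiments Sterilants to optimize (default all six).
#' @return The ideal-point table, invisibly.
#' @export
pipeline_optimize <- function(config = pipeline_config(), outdir,
                              experiments = sterilants()) {
  cf_model <- read_mlp_json(
    require_artifact(outdir, "cf_model.json", "pipeline_train()")
  )
  ev_model <- read_mlp_json(
    require_artifact(outdir, "ev_model.json", "pipeline_train()")
  )
  records <- read_records_csv(
    require_artifact(outdir, "records.csv", "pipeline_reconstruct()")
  )
  refs <- compute_refs(records)

  ideals <- do.call(rbind, lapply(experiments, function(s) {
    cfg <- config$nsga
    cfg$seed <- derive_seed(config$seed, 20 + match(s, sterilants()))
    opt <- optimize_experiment(cf_model, ev_model, s, cfg,
                               time_bounds = config$time_bounds, refs = refs)
    utils::write.csv(opt$front,
                     stage_file(outdir, paste0("front_", s, ".csv")),
                     row.names = FALSE)
    opt$ideal
  }))
  utils::write.csv(ideals, stage_file(outdir, "ideal_points.csv"),
                   row.names = FALSE)
  invisible(ideals)
}

#' Pipeline stage: input-importance analysis
#'
#' Reads the train/test partitions and writes `sensitivity.csv` with the
#' VSE/VSR ranking for both responses.
#'
#' @inheritParams pipeline_reconstruct
#' @return A list of two `sensitivity_report`s (`cf`, `ev`), invisibly.
#' @export
pipeline_sensitivity <- function(config = pipeline_config(), outdir) {
  train <- read_records_csv(
    require_artifact(outdir, "train.csv", "pipeline_train()")
  )
  test <- read_records_csv(
    require_artifact(outdir, "test.csv", "pipeline_train()")
  )
  split <- structure(
    list(train = train, test = test, fraction = config$fraction,
         seed = config$seed, accepted_seed = NA),
    class = "dataset_split"
  )
  reports <- lapply(c(cf = "cf", ev = "ev"), function(target) {
    variable_sensitivity(split, target, n_hidden = config$sens_hidden,
                         seed = derive_seed(config$seed, 30),
                         control = config$lm)
  })
  write_sensitivity_csv(reports, stage_file(outdir, "sensitivity.csv"))
  invisible(reports)
}

#' Pipeline stage: assemble the run report
#'
#' Gathers the stage outputs into one list mirroring the published
#' summary tables (fit statistics, per-experiment ideal points,
#' sensitivity ranks) side by side with the shipped reference values,
#' and writes it as `report.json`.
#'
#' @inheritParams pipeline_reconstruct
#' @return The report list, invisibly.
#' @export
pipeline_report <- function(config = pipeline_config(), outdir) {
  metrics <- utils::read.csv(
    require_artifact(outdir, "metrics.csv", "pipeline_train()")
  )
  ideals <- utils::read.csv(
    require_artifact(outdir, "ideal_points.csv", "pipeline_optimize()")
  )
  sens <- utils::read.csv(
    require_artifact(outdir, "sensitivity.csv", "pipeline_sensitivity()")
  )
  report <- list(
    config = config_payload(config),
    fit_metrics = metrics,
    ideal_points = ideals,
    sensitivity = sens,
    reference = lapply(reported_benchmarks(), identity)
  )
  jsonlite::write_json(report, stage_file(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}

#' Run the full pipeline
#'
#' Convenience wrapper running all five stages in order.
#'
#' @inheritParams pipeline_reconstruct
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  pipeline_reconstruct(config, outdir)
  pipeline_train(config, outdir)
  pipeline_optimize(config, outdir)
  pipeline_sensitivity(config, outdir)
  pipeline_report(config, outdir)
}

#' Reference benchmark tables of the original study
#'
#' The summary results the original screening study reported for its own
#' fitted models: fit statistics of the surrogates, ideal-point
#' protocols per sterilant, sensitivity ranks, and the wet-lab
#' validation outcomes of the optimized protocols. Shipped purely for
#' side-by-side comparison with a run's outputs; never used in any
#' computation.
#'
#' @return A named list of data frames: `fit_statistics`,
#'   `ideal_points`, `sensitivity_ranks`, `validation`.
#' @export
reported_benchmarks <- function() {
  dir <- system.file("extdata", "reference", package = "sterilopt")
  files <- c(fit_statistics = "reported_fit_statistics.csv",
             ideal_points = "reported_ideal_points.csv",
             sensitivity_ranks = "reported_sensitivity_ranks.csv",
             validation = "reported_validation.csv")
  lapply(files, function(f) {
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  })
}
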