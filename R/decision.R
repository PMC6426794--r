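# Compromise-solution selection on the Pareto front (ideal-point
# distance) and input-importance ranking by variable sensitivity ratios.

#' Ideal-point reference values from observed data
#'
#' The ideal point of the optimization is the objective pair
#' (lowest observed contamination frequency, highest observed explant
#' viability). Over the full reconstructed dataset this is (0, 100).
#'
#' @param records Record data frame with `cf_pct` and `ev_pct` columns.
#' @return A list with `cf_ref` and `ev_ref` (percent).
#' @export
compute_refs <- function(records) {
  if (nrow(records) == 0) stop("`records` is empty")
  list(cf_ref = min(records$cf_pct), ev_ref = max(records$ev_pct))
}

#' Select the compromise solution nearest the ideal point
#'
#' Among the front members, returns the one minimizing the squared
#' distance `(CF - cf_ref)^2 + (EV - ev_ref)^2`. Both objectives are
#' percentages on the same scale, so no rescaling is applied. Ties are
#' broken by lower predicted CF, then by shorter immersion time, then
#' by lower concentration, which makes the selection invariant to the
#' ordering of the front.
#'
#' @param front A data frame with columns `cf_pred`, `ev_pred` and
#'   `time_min` (as produced by [optimize_experiment()]), or a
#'   `pareto_front` from [nsga2_evolve()] whose objectives are
#'   `(CF, -EV)`.
#' @param refs A list with `cf_ref` and `ev_ref`, from [compute_refs()].
#' @return The selected row of the front (one-row data frame) with the
#'   squared `ideal_distance2` appended.
#' @export
select_ideal <- function(front, refs = list(cf_ref = 0, ev_ref = 100)) {
  if (inherits(front, "pareto_front")) {
    front <- data.frame(
      concentration = front$decisions[, 1],
      time_min = front$decisions[, 2],
      cf_pred = front$objectives[, 1],
      ev_pred = -front$objectives[, 2]
    )
  }
  if (nrow(front) == 0) stop("empty front")
  d2 <- (front$cf_pred - refs$cf_ref)^2 + (front$ev_pred - refs$ev_ref)^2
  ord <- order(d2, front$cf_pred,
               if (!is.null(front$time_min)) front$time_min else d2,
               if (!is.null(front$concentration)) front$concentration else d2)
  out <- front[ord[1], , drop = FALSE]
  out$ideal_distance2 <- d2[ord[1]]
  rownames(out) <- NULL
  out
}

#' Rank input importance by variable sensitivity ratios
#'
#' The importance of each of the seven inputs is measured by what the
#' model loses without it: the baseline network is trained on the
#' training partition with all inputs and scored by RMSE over the entire
#' dataset (training and testing together); then, for each input, a
#' network of the same architecture is retrained with that input's
#' column removed and scored the same way, giving the variable
#' sensitivity error VSE. The variable sensitivity ratio is
#' `VSR = VSE / baseline RMSE`; the larger the ratio, the more the model
#' depends on that input. Inputs are ranked by descending VSR
#' (rank 1 = most important).
#'
#' @param split A `dataset_split` from [split_train_test()].
#' @param target `"cf"` or `"ev"`.
#' @param n_hidden Hidden-layer size used for the baseline and every
#'   refit.
#' @param seed Integer seed; each refit uses a seed derived from it, so
#'   the report is reproducible.
#' @param control An [lm_control()].
#' @return An object of class `sensitivity_report`: a data frame with
#'   one row per input (`input`, `vse`, `vsr`, `rank`) and the baseline
#'   RMSE in attribute `"baseline_rmse"`.
#' @export
variable_sensitivity <- function(split, target = c("cf", "ev"), n_hidden = 7,
                                 seed = 1, control = lm_control()) {
  target <- match.arg(target)
  all_records <- rbind(split$train, split$test)
  col <- paste0(target, "_pct")

  baseline <- train_mlp(split$train, target, n_hidden = n_hidden,
                        seed = derive_seed(seed, 0), control = control)
  baseline_rmse <- rmse(all_records[[col]], mlp_predict(baseline, all_records))

  inputs <- input_names()
  vse <- vapply(seq_along(inputs), function(v) {
    feats <- inputs[-v]
    fit <- tryCatch(
      train_mlp(split$train, target, n_hidden = n_hidden,
                seed = derive_seed(seed, v), control = control,
                features = feats),
      error = function(e) {
        stop("sensitivity refit failed for input '", inputs[v], "': ",
             conditionMessage(e))
      }
    )
    rmse(all_records[[col]], mlp_predict(fit, all_records))
  }, numeric(1))

  vsr <- vse / baseline_rmse
  out <- data.frame(
    input = inputs, vse = vse, vsr = vsr,
    rank = rank(-vsr, ties.method = "first"),
    stringsAsFactors = FALSE
  )
  attr(out, "baseline_rmse") <- baseline_rmse
  attr(out, "target") <- target
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("sensitivity_report [", toupper(attr(x, "target")), "], baseline RMSE ",
      signif(attr(x, "baseline_rmse"), 4), "\n", sep = "")
  print.data.frame(x[order(x$rank), ], row.names = FALSE)
  invisible(x)
}

#' Write a sensitivity report as CSV
#'
#' Columns `output,input,vse,vsr,rank`.
#'
#' @param report A `sensitivity_report` (or a list of them).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_sensitivity_csv <- function(report, path) {
  reports <- if (inherits(report, "sensitivity_report")) list(report) else report
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(output = toupper(attr(r, "target")),
               input = r$input, vse = r$vse, vsr = r$vsr, rank = r$rank,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
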