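# Reconstruction of the replicate-level dataset from the printed
# treatment means, and the train/test split with range-containment check.

#' Reconstruct replicate-level records from the screen tables
#'
#' The surrogate models are trained on individual replicates, but only
#' treatment means and standard errors are printed. This reconstructs a
#' replicate-level dataset: each nonzero-dose cell of the six experiments
#' becomes one treatment, and all zero-dose cells collapse to a single
#' pooled control (all six sterilant inputs 0, immersion time 10 min,
#' CF 100, EV 0 — the identical outcome every experiment printed at zero
#' dose, at every time). Each treatment emits `replicates` records whose
#' CF and EV are drawn from Normal(mean, noise_scale * se * sqrt(replicates))
#' — the per-observation dispersion implied by a standard error of a mean
#' of `replicates` sub-sets — and clipped to \[0, 100\].
#'
#' With defaults (3 replicates) the dataset has 73 treatments x 3 = 219
#' records.
#'
#' @param rows Treatment-mean table as returned by [load_screen_tables()].
#' @param replicates Records per treatment (default 3).
#' @param noise_scale Multiplier on the SE-implied dispersion; 0 gives
#'   noise-free records equal to the treatment means.
#' @param seed Integer seed; the reconstruction is deterministic given it.
#' @return A data frame with columns `treatment_id`, `replicate`, the
#'   seven inputs `naocl_pct`, `caclo2_pct`, `hgcl2_pct`, `agno3_pct`,
#'   `h2o2_pct`, `ns_mgL`, `time_min`, and the responses `cf_pct`,
#'   `ev_pct`.
#' @examples
#' rec <- reconstruct_records(seed = 1)
#' nrow(rec)  # 219
#' @export
reconstruct_records <- function(rows = load_screen_tables(), replicates = 3,
                                noise_scale = 1, seed = 1) {
  if (!is.numeric(replicates) || length(replicates) != 1 ||
      replicates < 1 || replicates != round(replicates)) {
    stop("`replicates` must be a positive integer")
  }
  if (!is.numeric(noise_scale) || length(noise_scale) != 1 || noise_scale < 0) {
    stop("`noise_scale` must be a non-negative number")
  }

  nonzero <- rows[rows$concentration > 0, , drop = FALSE]
  treatments <- data.frame(
    treatment_id = paste0(nonzero$sterilant, "_",
                          nonzero$concentration, "x", nonzero$time_min),
    sterilant = nonzero$sterilant,
    concentration = nonzero$concentration,
    time_min = nonzero$time_min,
    cf_mean = nonzero$cf_mean, cf_se = nonzero$cf_se,
    ev_mean = nonzero$ev_mean, ev_se = nonzero$ev_se,
    stringsAsFactors = FALSE
  )
  # Pooled control: zero dose behaves identically in every experiment at
  # every time, so time carries no information there; encode once at the
  # modal mid level (10 min).
  control <- data.frame(
    treatment_id = "control", sterilant = NA_character_,
    concentration = 0, time_min = 10,
    cf_mean = 100, cf_se = 0, ev_mean = 0, ev_se = 0,
    stringsAsFactors = FALSE
  )
  treatments <- rbind(treatments, control)

  n_trt <- nrow(treatments)
  x <- matrix(0, nrow = n_trt, ncol = 7,
              dimnames = list(NULL, input_names()))
  for (i in seq_len(n_trt)) {
    if (!is.na(treatments$sterilant[i])) {
      x[i, sterilant_column(treatments$sterilant[i])] <-
        treatments$concentration[i]
    }
  }
  x[, "time_min"] <- treatments$time_min

  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_trt), function(i) {
      sd_cf <- noise_scale * treatments$cf_se[i] * sqrt(replicates)
      sd_ev <- noise_scale * treatments$ev_se[i] * sqrt(replicates)
      cf <- clip(stats::rnorm(replicates, treatments$cf_mean[i], sd_cf))
      ev <- clip(stats::rnorm(replicates, treatments$ev_mean[i], sd_ev))
      cbind(
        data.frame(treatment_id = treatments$treatment_id[i],
                   replicate = seq_len(replicates),
                   stringsAsFactors = FALSE),
        as.data.frame(x[rep(i, replicates), , drop = FALSE]),
        data.frame(cf_pct = cf, ev_pct = ev)
      )
    }))
    rownames(out) <- NULL
    out
  })
}

#' Split records into training and testing partitions
#'
#' Random split at the replicate level with the size rule
#' `|train| = ceiling(fraction * N)` (219 records at the default 0.75
#' fraction split 165/54). Because the surrogates must interpolate rather
#' than extrapolate, a candidate split is accepted only if, for every
#' input dimension with nonzero variance, the test range lies within the
#' training range; otherwise the split is redrawn from a derived seed, up
#' to `max_retries` times.
#'
#' @param records Record data frame from [reconstruct_records()].
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @param max_retries Redraw budget for the containment check.
#' @return An object of class `dataset_split`: a list with `train` and
#'   `test` data frames, and the `fraction`, the requested `seed` and the
#'   `accepted_seed` that produced the returned split.
#' @examples
#' sp <- split_train_test(reconstruct_records(seed = 1), seed = 1)
#' c(nrow(sp$train), nrow(sp$test))  # 165 54
#' @export
split_train_test <- function(records, fraction = 0.75, seed = 1,
                             max_retries = 200) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be strictly between 0 and 1")
  }
  n <- nrow(records)
  n_train <- ceiling(fraction * n)
  xs <- as.matrix(records[, input_names(), drop = FALSE])
  varying <- apply(xs, 2, function(col) diff(range(col)) > 0)

  for (attempt in seq_len(max_retries + 1)) {
    seed_k <- if (attempt == 1) as.integer(seed) else derive_seed(seed, attempt)
    idx <- with_seed(seed_k, sample.int(n, n_train))
    train_x <- xs[idx, , drop = FALSE]
    test_x <- xs[-idx, , drop = FALSE]
    bad <- names(which(vapply(which(varying), function(j) {
      min(test_x[, j]) < min(train_x[, j]) ||
        max(test_x[, j]) > max(train_x[, j])
    }, logical(1))))
    if (length(bad) == 0) {
      out <- list(
        train = records[idx, , drop = FALSE],
        test = records[-idx, , drop = FALSE],
        fraction = fraction,
        seed = seed,
        accepted_seed = seed_k
      )
      rownames(out$train) <- rownames(out$test) <- NULL
      class(out) <- "dataset_split"
      return(out)
    }
    last_bad <- bad
  }
  stop("no split satisfying range containment within ", max_retries,
       " retries; offending dimension(s): ", paste(last_bad, collapse = ", "))
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("dataset_split: ", nrow(x$train), " train / ", nrow(x$test),
      " test records (fraction ", x$fraction, ", seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Read and write replicate-level records as CSV
#'
#' Plain UTF-8 CSV with '.' decimal separator and the canonical header
#' `treatment_id,replicate,naocl_pct,caclo2_pct,hgcl2_pct,agno3_pct,`
#' `h2o2_pct,ns_mgL,time_min,cf_pct,ev_pct`.
#'
#' @param records Record data frame.
#' @param path File path.
#' @return `write_records_csv` returns the path invisibly;
#'   `read_records_csv` returns the record data frame.
#' @export
write_records_csv <- function(records, path) {
  cols <- c("treatment_id", "replicate", input_names(), "cf_pct", "ev_pct")
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("treatment_id", "replicate", input_names(), "cf_pct", "ev_pct")
  missing <- setdiff(expected, names(out))
  if (length(missing) > 0) {
    stop("records CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  out[, expected]
}
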