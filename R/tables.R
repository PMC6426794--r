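# Embedded factorial screening tables: mean +/- SE of contamination
# frequency (CF, %) and explant viability (EV, %) for every
# sterilant-concentration x immersion-time cell of a published
# chrysanthemum leaf-explant sterilization screen (six experiments,
# five concentrations x three times each).

#' Sterilant identifiers
#'
#' The six sterilants screened, in the canonical input-column order used
#' throughout the package: sodium hypochlorite, calcium hypochlorite,
#' mercuric chloride, silver nitrate, hydrogen peroxide and nano-silver.
#'
#' @return Character vector of length six.
#' @export
sterilants <- function() {
  c("NaOCl", "CaClO2", "HgCl2", "AgNO3", "H2O2", "NS")
}

# Names of the seven model inputs (six doses + immersion time).
input_names <- function() {
  c("naocl_pct", "caclo2_pct", "hgcl2_pct", "agno3_pct",
    "h2o2_pct", "ns_mgL", "time_min")
}

# Map a sterilant id to its input column.
sterilant_column <- function(sterilant) {
  cols <- c(NaOCl = "naocl_pct", CaClO2 = "caclo2_pct", HgCl2 = "hgcl2_pct",
            AgNO3 = "agno3_pct", H2O2 = "h2o2_pct", NS = "ns_mgL")
  sterilant <- match.arg(sterilant, names(cols))
  unname(cols[[sterilant]])
}

# One experiment block: matrix columns conc, time, cf_mean, cf_se,
# ev_mean, ev_se; 15 rows (5 concentrations x 3 times).
table_block <- function(sterilant) {
  blocks <- list(
    NaOCl = c(
      0.0,  5, 100.00, 0.00,   0.00, 0.00,
      0.0, 10, 100.00, 0.00,   0.00, 0.00,
      0.0, 15, 100.00, 0.00,   0.00, 0.00,
      0.5,  5,  57.78, 2.22,  33.33, 3.85,
      0.5, 10,  44.45, 2.22,  42.22, 5.88,
      0.5, 15,  31.11, 2.22,  66.67, 0.00,
      1.0,  5,  35.55, 2.22,  62.22, 2.22,
      1.0, 10,  22.22, 2.22,  71.11, 2.22,
      1.0, 15,  13.33, 3.85,  80.00, 6.67,
      1.5,  5,  15.55, 2.22,  77.78, 2.22,
      1.5, 10,   4.45, 2.22,  93.33, 3.85,
      1.5, 15,   0.00, 0.00, 100.00, 0.00,
      2.0,  5,   8.89, 2.22,  84.44, 4.44,
      2.0, 10,   0.00, 0.00,  84.44, 5.88,
      2.0, 15,   0.00, 0.00,  71.11, 5.88),
    CaClO2 = c(
      0.0,  5, 100.00, 0.00,   0.00, 0.00,
      0.0, 10, 100.00, 0.00,   0.00, 0.00,
      0.0, 15, 100.00, 0.00,   0.00, 0.00,
      8.5,  5,  48.89, 2.22,  46.67, 3.85,
      8.5, 10,  37.78, 2.22,  57.78, 2.22,
      8.5, 15,  28.89, 2.22,  66.67, 3.85,
      9.0,  5,  37.78, 2.22,  57.78, 2.22,
      9.0, 10,  20.00, 3.85,  73.34, 0.00,
      9.0, 15,  11.11, 2.22,  82.22, 2.22,
      9.5,  5,  15.55, 2.22,  80.00, 3.85,
      9.5, 10,   6.67, 3.85,  91.11, 2.22,
      9.5, 15,   0.00, 0.00,  95.56, 2.22,
     10.0,  5,   0.00, 0.00,  97.78, 2.22,
     10.0, 10,   0.00, 0.00,  91.11, 2.22,
     10.0, 15,   0.00, 0.00,  75.56, 8.02),
    HgCl2 = c(
      0.00, 2.5, 100.00, 0.00,   0.00, 0.00,
      0.00, 5.0, 100.00, 0.00,   0.00, 0.00,
      0.00, 7.5, 100.00, 0.00,   0.00, 0.00,
      0.25, 2.5,  15.56, 4.45,  64.44, 4.45,
      0.25, 5.0,  11.11, 2.22,  62.22, 4.45,
      0.25, 7.5,   4.44, 2.22,  44.44, 2.22,
      0.50, 2.5,   4.44, 2.22,  55.56, 2.22,
      0.50, 5.0,   2.22, 2.22,  42.22, 4.45,
      0.50, 7.5,   0.00, 0.00,  28.89, 2.22,
      0.75, 2.5,   0.00, 0.00,  24.44, 4.45,
      0.75, 5.0,   0.00, 0.00,   8.89, 4.45,
      0.75, 7.5,   0.00, 0.00,   4.44, 2.22,
      1.00, 2.5,   0.00, 0.00,   4.44, 2.22,
      1.00, 5.0,   0.00, 0.00,   2.22, 2.22,
      1.00, 7.5,   0.00, 0.00,   0.00, 0.00),
    AgNO3 = c(
      0.00,  5, 100.00, 0.00,   0.00, 0.00,
      0.00, 10, 100.00, 0.00,   0.00, 0.00,
      0.00, 15, 100.00, 0.00,   0.00, 0.00,
      0.25,  5,  88.89, 2.22,  11.11, 2.22,
      0.25, 10,  82.22, 2.22,  13.33, 3.85,
      0.25, 15,  75.56, 2.22,  22.22, 4.45,
      0.50,  5,  77.78, 2.22,  22.22, 2.22,
      0.50, 10,  71.11, 2.22,  22.22, 2.22,
      0.50, 15,  66.67, 3.85,  24.44, 2.22,
      0.75,  5,  71.11, 4.45,  26.67, 6.68,
      0.75, 10,  62.22, 2.22,  35.56, 4.45,
      0.75, 15,  53.33, 6.68,  40.00, 6.68,
      1.00,  5,  64.44, 4.45,  31.11, 5.88,
      1.00, 10,  46.67, 3.85,  40.00, 6.68,
      1.00, 15,  37.78, 2.22,  57.78, 2.22),
    H2O2 = c(
      0.0,  5, 100.00, 0.00,   0.00, 0.00,
      0.0, 10, 100.00, 0.00,   0.00, 0.00,
      0.0, 15, 100.00, 0.00,   0.00, 0.00,
     10.5,  5,  68.89, 2.22,  31.11, 2.22,
     10.5, 10,  62.22, 2.22,  35.56, 2.22,
     10.5, 15,  51.11, 2.22,  46.67, 0.00,
     11.0,  5,  53.33, 3.85,  42.22, 5.88,
     11.0, 10,  46.67, 3.85,  48.89, 5.88,
     11.0, 15,  42.22, 2.22,  57.78, 2.22,
     11.5,  5,  44.44, 2.22,  51.11, 4.45,
     11.5, 10,  37.78, 2.22,  60.00, 0.00,
     11.5, 15,  17.78, 4.45,  75.56, 4.45,
     12.0,  5,  15.56, 2.22,  82.22, 2.22,
     12.0, 10,   6.67, 3.85,  91.11, 2.22,
     12.0, 15,   2.22, 2.22,  97.78, 2.22),
    NS = c(
      0.0,  5.0, 100.00, 0.00,   0.00, 0.00,
      0.0,  7.5, 100.00, 0.00,   0.00, 0.00,
      0.0, 10.0, 100.00, 0.00,   0.00, 0.00,
      2.5,  5.0,  80.00, 6.68,  17.78, 4.44,
      2.5,  7.5,  71.11, 2.22,  26.67, 3.85,
      2.5, 10.0,  62.22, 2.22,  35.56, 2.22,
      5.0,  5.0,  64.44, 4.44,  35.56, 4.44,
      5.0,  7.5,  57.78, 2.22,  40.00, 3.85,
      5.0, 10.0,  51.11, 4.44,  44.44, 2.22,
      7.5,  5.0,  55.56, 4.45,  44.44, 2.22,
      7.5,  7.5,  44.44, 2.22,  55.56, 2.22,
      7.5, 10.0,  37.78, 2.22,  62.22, 2.22,
     10.0,  5.0,  35.56, 2.22,  64.44, 2.22,
     10.0,  7.5,  17.78, 4.44,  82.22, 4.44,
     10.0, 10.0,  15.56, 2.22,  84.44, 2.22)
  )
  m <- matrix(blocks[[sterilant]], ncol = 6, byrow = TRUE)
  colnames(m) <- c("concentration", "time_min",
                   "cf_mean", "cf_se", "ev_mean", "ev_se")
  m
}

#' Treatment-mean table of the sterilization screen
#'
#' Returns the embedded interaction cells (concentration x immersion time)
#' of all six factorial experiments: mean and standard error of
#' contamination frequency (CF, %) and explant viability (EV, %) for each
#' of the 90 treatment cells (6 sterilants x 5 concentrations x 3 times).
#' Concentrations are percent (w/v or v/v) for all sterilants except
#' nano-silver (NS), which is in mg/L.
#'
#' @return A data frame with columns `sterilant`, `concentration`,
#'   `time_min`, `cf_mean`, `cf_se`, `ev_mean`, `ev_se`; one row per
#'   printed interaction cell (90 rows).
#' @examples
#' tab <- load_screen_tables()
#' subset(tab, sterilant == "NaOCl" & concentration == 1.5 & time_min == 15)
#' @export
load_screen_tables <- function() {
  out <- do.call(rbind, lapply(sterilants(), function(s) {
    block <- as.data.frame(table_block(s))
    cbind(data.frame(sterilant = s, stringsAsFactors = FALSE), block)
  }))
  rownames(out) <- NULL
  out
}

#' Concentration and time domains of each experiment
#'
#' The box constraints used during optimization: the lower and upper bound
#' of each decision variable are the extremes of the concentration and
#' immersion-time levels actually screened for that sterilant.
#'
#' @param sterilant One of `sterilants()`.
#' @return A list with elements `sterilant`, `conc_levels`, `time_levels`,
#'   `conc_bounds` and `time_bounds` (each bound a length-2 numeric
#'   `c(lo, hi)`).
#' @examples
#' experiment_domain("NaOCl")$conc_bounds
#' @export
experiment_domain <- function(sterilant) {
  sterilant <- match.arg(sterilant, sterilants())
  block <- table_block(sterilant)
  conc <- sort(unique(block[, "concentration"]))
  tim <- sort(unique(block[, "time_min"]))
  list(
    sterilant = sterilant,
    conc_levels = conc,
    time_levels = tim,
    conc_bounds = range(conc),
    time_bounds = range(tim)
  )
}

# Global immersion-time range across all six experiments (2.5-15 min).
global_time_bounds <- function() {
  rng <- range(unlist(lapply(sterilants(), function(s) {
    experiment_domain(s)$time_levels
  })))
  rng
}

#' Export the embedded screen tables as CSV
#'
#' Writes the 90 interaction cells returned by [load_screen_tables()] to a
#' CSV file for external inspection.
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_screen_tables_csv <- function(path) {
  utils::write.csv(load_screen_tables(), path, row.names = FALSE)
  invisible(path)
}
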