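# Affine [-1, 1] range scaling fitted on training data. The hyperbolic
# tangent hidden layer saturates quickly outside a few units of zero, so
# inputs and targets are mapped onto the training min/max box before any
# network sees them.

#' Fit a min-max scaler to training data
#'
#' Maps every column of `x` affinely onto \[-1, 1\] using the column
#' minimum and maximum. Columns with zero range map to 0.
#'
#' @param x Numeric matrix (or vector, treated as one column).
#' @return An object of class `range_scaler`.
#' @export
scale_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("cannot fit a scaler to zero rows")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  out <- list(lo = lo, hi = hi, width = hi - lo)
  class(out) <- "range_scaler"
  out
}

#' Apply or invert a fitted scaler
#'
#' `scale_apply` maps data into \[-1, 1\]; `scale_invert` maps scaled
#' values back to the original units. The two are exact inverses on any
#' finite input; zero-range dimensions map to 0 and invert to the
#' training constant.
#'
#' @param scaler A `range_scaler` from [scale_fit()].
#' @param x Matrix or vector in original units (`scale_apply`) or in
#'   scaled units (`scale_invert`).
#' @return Matrix of the same shape as `x`.
#' @export
scale_apply <- function(scaler, x) {
  check_scaler(scaler)
  x <- as_scaler_matrix(scaler, x)
  out <- x
  for (j in seq_along(scaler$lo)) {
    out[, j] <- if (scaler$width[j] > 0) {
      2 * (x[, j] - scaler$lo[j]) / scaler$width[j] - 1
    } else {
      0
    }
  }
  out
}

#' @rdname scale_apply
#' @export
scale_invert <- function(scaler, x) {
  check_scaler(scaler)
  x <- as_scaler_matrix(scaler, x)
  out <- x
  for (j in seq_along(scaler$lo)) {
    out[, j] <- if (scaler$width[j] > 0) {
      (x[, j] + 1) / 2 * scaler$width[j] + scaler$lo[j]
    } else {
      scaler$lo[j]
    }
  }
  out
}

check_scaler <- function(scaler) {
  if (!inherits(scaler, "range_scaler")) {
    stop("scaler has not been fitted; call scale_fit() first")
  }
  invisible(scaler)
}

as_scaler_matrix <- function(scaler, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = length(scaler$lo), byrow = TRUE)
  if (ncol(x) != length(scaler$lo)) {
    stop("input has ", ncol(x), " columns but the scaler was fitted on ",
         length(scaler$lo))
  }
  x
}
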