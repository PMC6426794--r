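# Single-hidden-layer perceptron surrogates trained by
# Levenberg-Marquardt. One network per response (CF or EV): hyperbolic
# tangent sigmoid hidden layer, linear output,
#   yhat = b0 + sum_j w2_j * tanh(sum_i W1_ji x_i + b1_j)
# fitted to minimize the mean squared residual over the training pairs.
# All fitting happens in [-1, 1] scaled space (see scaler.R); predictions
# are returned in percent.

#' Levenberg-Marquardt training settings
#'
#' @param lambda0 Initial damping factor (> 0).
#' @param lambda_dec,lambda_inc Factors by which the damping is divided
#'   after an accepted step and multiplied after a rejected one.
#' @param lambda_max Damping ceiling; training stops once no acceptable
#'   step exists below it.
#' @param max_epochs Maximum number of accepted iterations.
#' @param grad_tol Stop when the infinity norm of the loss gradient falls
#'   below this.
#' @param n_starts Independent random initializations; the best fit
#'   (lowest validation loss when early stopping is on, lowest training
#'   loss otherwise) is kept.
#' @param init_range Half-width of the uniform weight initialization.
#' @param val_frac Fraction of the training records held out as an
#'   early-stopping validation set (0 disables early stopping and
#'   trains on everything).
#' @param patience Accepted steps without validation improvement before
#'   training stops (only with `val_frac > 0`); the weights with the
#'   best validation loss are returned.
#' @return A list of class `lm_control`.
#' @export
lm_control <- function(lambda0 = 1e-3, lambda_dec = 10, lambda_inc = 10,
                       lambda_max = 1e10, max_epochs = 1000, grad_tol = 1e-7,
                       n_starts = 4, init_range = 0.5, val_frac = 0.2,
                       patience = 6) {
  stopifnot(lambda0 > 0, lambda_dec > 1, lambda_inc > 1,
            lambda_max > lambda0, max_epochs >= 1, grad_tol > 0,
            n_starts >= 1, init_range > 0, val_frac >= 0, val_frac < 0.5,
            patience >= 1)
  structure(as.list(environment()), class = "lm_control")
}

# Pack / unpack the flattened parameter vector. Layout: vec(W1) stacked
# input-dimension-major (column i of inputs contributes m entries), then
# hidden biases b1, output weights w2, output bias b0.
unpack_theta <- function(theta, m, n) {
  list(
    W1 = matrix(theta[seq_len(m * n)], nrow = m, ncol = n),
    b1 = theta[m * n + seq_len(m)],
    w2 = theta[m * n + m + seq_len(m)],
    b0 = theta[m * (n + 2) + 1]
  )
}

pack_theta <- function(W1, b1, w2, b0) c(as.vector(W1), b1, w2, b0)

# Forward pass in scaled space: Xs is K x n, returns list(yhat, Z).
mlp_forward_scaled <- function(theta, m, n, Xs) {
  p <- unpack_theta(theta, m, n)
  Z <- tanh(Xs %*% t(p$W1) + matrix(p$b1, nrow(Xs), m, byrow = TRUE))
  list(yhat = as.vector(Z %*% p$w2 + p$b0), Z = Z)
}

# Jacobian of the residual vector (yhat - y) with respect to theta,
# assembled from backpropagated derivatives: K x P with
# P = m*(n+2) + 1.
mlp_jacobian <- function(theta, m, n, Xs, Z) {
  w2 <- unpack_theta(theta, m, n)$w2
  D <- (1 - Z^2) * matrix(w2, nrow(Xs), m, byrow = TRUE)
  cbind(
    D[, rep(seq_len(m), times = n), drop = FALSE] *
      Xs[, rep(seq_len(n), each = m), drop = FALSE],
    D, Z, 1
  )
}

#' Mean squared prediction error
#'
#' The training objective: the mean of squared residuals between observed
#' and predicted values.
#'
#' @param y,yhat Equal-length numeric vectors of observed and predicted
#'   values.
#' @return A single non-negative number.
#' @examples
#' mlp_loss(c(0, 0), c(3, 4))  # 12.5
#' @export
mlp_loss <- function(y, yhat) {
  if (length(y) == 0) stop("empty input")
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  mean((y - yhat)^2)
}

# Core LM fit on raw matrices (single start). Xv/yv, when non-NULL,
# form the early-stopping validation set: the weights with the lowest
# validation loss are returned and training stops after `patience`
# accepted steps without validation improvement. Returns theta and the
# training state.
lm_fit_once <- function(Xs, ys, m, seed, control, Xv = NULL, yv = NULL) {
  n <- ncol(Xs)
  k <- nrow(Xs)
  n_par <- m * (n + 2) + 1
  theta <- with_seed(seed, stats::runif(n_par, -control$init_range,
                                        control$init_range))
  fw <- mlp_forward_scaled(theta, m, n, Xs)
  r <- fw$yhat - ys
  e <- mean(r^2)
  if (!is.finite(e)) stop("non-finite loss at initialization")
  use_val <- !is.null(Xv)
  val_loss <- function(th) {
    mean((mlp_forward_scaled(th, m, n, Xv)$yhat - yv)^2)
  }
  best_val <- if (use_val) val_loss(theta) else NA_real_
  best_theta <- theta
  stale <- 0
  lambda <- control$lambda0
  history <- e
  epoch <- 0
  stop_reason <- "max_epochs"

  while (epoch < control$max_epochs) {
    jac <- mlp_jacobian(theta, m, n, Xs, fw$Z)
    g <- crossprod(jac, r)                      # P x 1
    if (max(abs(2 * g / k)) < control$grad_tol) {
      stop_reason <- "grad_tol"
      break
    }
    jtj <- crossprod(jac)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(
        solve(jtj + diag(lambda, n_par), g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        theta_new <- theta - as.vector(step)
        fw_new <- mlp_forward_scaled(theta_new, m, n, Xs)
        r_new <- fw_new$yhat - ys
        e_new <- mean(r_new^2)
        if (is.finite(e_new) && e_new < e) {
          theta <- theta_new
          fw <- fw_new
          r <- r_new
          e <- e_new
          history <- c(history, e)
          lambda <- max(lambda / control$lambda_dec, 1e-12)
          accepted <- TRUE
        }
      }
      if (!accepted) {
        lambda <- lambda * control$lambda_inc
        if (lambda > control$lambda_max) break
      }
    }
    if (!accepted) {
      stop_reason <- "lambda_max"
      break
    }
    if (use_val) {
      v <- val_loss(theta)
      if (v < best_val) {
        best_val <- v
        best_theta <- theta
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= control$patience) {
          stop_reason <- "patience"
          epoch <- epoch + 1
          break
        }
      }
    }
    epoch <- epoch + 1
  }
  if (!use_val) best_theta <- theta
  list(theta = best_theta, E = e, val = best_val,
       score = if (use_val) best_val else e,
       lambda = lambda, epoch = epoch, history = history,
       stop_reason = stop_reason, seed = seed)
}

#' Train an MLP surrogate by Levenberg-Marquardt
#'
#' Fits a single-output three-layer perceptron to one response column of
#' a record data frame. Inputs and the target are range-scaled to
#' \[-1, 1\] on the training data; weights are initialized uniformly from
#' the seed; steps `delta = -(J'J + lambda I)^{-1} J'r` are accepted only
#' when the training loss decreases, so the accepted-step loss history is
#' monotone non-increasing. Training stops at the epoch budget, when the
#' gradient norm falls under `grad_tol`, or when the damping exceeds
#' `lambda_max` without an acceptable step. With the default
#' `val_frac > 0`, a held-out slice of the training records additionally
#' early-stops each run and the returned weights are the
#' best-validation snapshot — the standard guard against noise-fitting
#' in damped least-squares network training.
#'
#' @param records Training records (see [reconstruct_records()]).
#' @param target `"cf"` or `"ev"`.
#' @param n_hidden Hidden-layer size (see [select_architecture()]).
#' @param seed Integer seed; the fit is fully reproducible from it.
#' @param control An [lm_control()] list.
#' @param features Input columns to use (default all seven); the
#'   sensitivity analysis refits with one column removed.
#' @return An object of class `mlp_surrogate` with the weights, the
#'   attached scalers and a `state` list (final loss `E`, damping,
#'   epochs, accepted-loss `history`, stop reason, seed).
#' @export
train_mlp <- function(records, target = c("cf", "ev"), n_hidden = 7,
                      seed = 1, control = lm_control(),
                      features = input_names()) {
  target <- match.arg(target)
  if (n_hidden < 1 || n_hidden != round(n_hidden)) {
    stop("`n_hidden` must be a positive integer")
  }
  X <- as.matrix(records[, features, drop = FALSE])
  y <- records[[paste0(target, "_pct")]]
  if (nrow(unique(X)) < 2) stop("need at least 2 distinct training inputs")

  x_scaler <- scale_fit(X)
  y_scaler <- scale_fit(matrix(y, ncol = 1))
  Xs <- scale_apply(x_scaler, X)
  ys <- as.vector(scale_apply(y_scaler, matrix(y, ncol = 1)))

  Xv <- NULL
  yv <- NULL
  if (control$val_frac > 0) {
    n_all <- nrow(Xs)
    n_fit <- n_all - floor(control$val_frac * n_all)
    idx <- with_seed(derive_seed(seed, 55), sample.int(n_all, n_fit))
    Xv <- Xs[-idx, , drop = FALSE]
    yv <- ys[-idx]
    Xs <- Xs[idx, , drop = FALSE]
    ys <- ys[idx]
    if (nrow(unique(Xs)) < 2) stop("need at least 2 distinct training inputs")
  }

  fits <- lapply(seq_len(control$n_starts), function(s) {
    lm_fit_once(Xs, ys, n_hidden, derive_seed(seed, s), control,
                Xv = Xv, yv = yv)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "score"))]]
  p <- unpack_theta(best$theta, n_hidden, ncol(Xs))

  new_mlp(
    W1 = p$W1, b1 = p$b1, w2 = p$w2, b0 = p$b0,
    x_scaler = x_scaler, y_scaler = y_scaler,
    target = target, features = features,
    state = best[c("E", "val", "lambda", "epoch", "history", "stop_reason",
                   "seed")]
  )
}

#' Construct an MLP surrogate from explicit weights
#'
#' Mostly internal; exported so that small hand-specified networks can be
#' built directly. `NULL` scalers mean identity (no scaling).
#'
#' @param W1 Hidden weight matrix (`n_hidden` x `n_inputs`).
#' @param b1 Hidden biases (length `n_hidden`).
#' @param w2 Output weights (length `n_hidden`).
#' @param b0 Output bias (scalar).
#' @param x_scaler,y_scaler `range_scaler` objects or `NULL`.
#' @param target,features,state Metadata carried on the model.
#' @return An `mlp_surrogate`.
#' @export
new_mlp <- function(W1, b1, w2, b0, x_scaler = NULL, y_scaler = NULL,
                    target = NA_character_, features = NULL, state = NULL) {
  W1 <- as.matrix(W1)
  stopifnot(length(b1) == nrow(W1), length(w2) == nrow(W1), length(b0) == 1)
  if (!all(is.finite(W1)) || !all(is.finite(b1)) ||
      !all(is.finite(w2)) || !is.finite(b0)) {
    stop("non-finite weights")
  }
  structure(
    list(W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
         b0 = as.numeric(b0), x_scaler = x_scaler, y_scaler = y_scaler,
         target = target, features = features %||% colnames(W1),
         state = state),
    class = "mlp_surrogate"
  )
}

#' Predict from an MLP surrogate
#'
#' Deterministic forward pass: inputs are scaled with the training-input
#' scaler, passed through the tanh hidden layer and linear output, and
#' the result is inverse-scaled back to original units. Predictions are
#' not clipped here; clipping to \[0, 100\] is applied only inside the
#' optimization objectives.
#'
#' @param model An `mlp_surrogate`.
#' @param x A numeric vector of one input point, a matrix with one row
#'   per point, or a record data frame containing the model's feature
#'   columns.
#' @return Numeric vector of predictions.
#' @export
mlp_predict <- function(model, x) {
  stopifnot(inherits(model, "mlp_surrogate"))
  n <- ncol(model$W1)
  if (is.data.frame(x)) x <- as.matrix(x[, model$features, drop = FALSE])
  if (is.null(dim(x))) {
    if (length(x) != n) {
      stop("input has length ", length(x), " but the model expects ", n)
    }
    x <- matrix(x, ncol = n, byrow = TRUE)
  }
  if (ncol(x) != n) {
    stop("input has ", ncol(x), " columns but the model expects ", n)
  }
  if (!all(is.finite(x))) stop("non-finite input")
  Xs <- if (is.null(model$x_scaler)) x else scale_apply(model$x_scaler, x)
  Z <- tanh(Xs %*% t(model$W1) +
              matrix(model$b1, nrow(Xs), nrow(model$W1), byrow = TRUE))
  ys <- as.vector(Z %*% model$w2 + model$b0)
  if (is.null(model$y_scaler)) ys
  else as.vector(scale_invert(model$y_scaler, matrix(ys, ncol = 1)))
}

#' @export
predict.mlp_surrogate <- function(object, newdata, ...) {
  mlp_predict(object, newdata)
}

#' @export
print.mlp_surrogate <- function(x, ...) {
  cat("mlp_surrogate: ", ncol(x$W1), " inputs -> ", nrow(x$W1),
      " tanh units -> 1 linear output", sep = "")
  if (!is.na(x$target)) cat(" [target: ", toupper(x$target), "]", sep = "")
  if (!is.null(x$state)) {
    cat("\n  final training MSE (scaled): ", signif(x$state$E, 4),
        " after ", x$state$epoch, " epochs (", x$state$stop_reason, ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Coefficient of determination and root mean square error
#'
#' `r_squared` is `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`;
#' `rmse` is `sqrt(mean((y - yhat)^2))`. On a zero-variance target the
#' coefficient of determination is undefined and returned as `NA` with a
#' warning.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return A single number.
#' @export
r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("zero-variance target: R^2 is undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / sst
}

#' @rdname r_squared
#' @export
rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Evaluate a surrogate on a train/test split
#'
#' Computes the coefficient of determination and RMSE of raw (unclipped)
#' predictions on both partitions.
#'
#' @param model An `mlp_surrogate`.
#' @param split A `dataset_split`.
#' @param target `"cf"` or `"ev"`; defaults to the model's own target.
#' @return A data frame with one row per phase (`train`, `test`) and
#'   columns `target`, `phase`, `n`, `r2`, `rmse`.
#' @export
evaluate_mlp <- function(model, split, target = model$target) {
  target <- match.arg(target, c("cf", "ev"))
  col <- paste0(target, "_pct")
  do.call(rbind, lapply(c("train", "test"), function(phase) {
    recs <- split[[phase]]
    if (nrow(recs) == 0) stop("empty ", phase, " partition")
    y <- recs[[col]]
    yhat <- mlp_predict(model, recs)
    data.frame(target = target, phase = phase, n = length(y),
               r2 = r_squared(y, yhat), rmse = rmse(y, yhat),
               stringsAsFactors = FALSE)
  }))
}

#' Choose the hidden-layer size by internal cross-validation
#'
#' The field's rule-of-thumb sizes (the input count n, 2n, and log of the
#' training count) seed the candidate set. Each candidate is scored by
#' k-fold cross-validation inside the training records — trained on the
#' complement of each fold and scored by RMSE on the fold; the test
#' partition is never touched. The size with the lowest pooled
#' validation RMSE wins; ties go to the smallest network.
#'
#' @param records Training records.
#' @param target `"cf"` or `"ev"`.
#' @param candidates Integer vector of hidden-layer sizes.
#' @param seed Integer seed (fold assignment and all fits derive from it).
#' @param control An [lm_control()].
#' @param features Input columns.
#' @param folds Number of cross-validation folds.
#' @return The chosen size, with the validation table in attribute
#'   `"validation"`.
#' @export
select_architecture <- function(records, target = c("cf", "ev"),
                                candidates = c(3, 5, 7, 10, 14), seed = 1,
                                control = lm_control(),
                                features = input_names(), folds = 3) {
  target <- match.arg(target)
  if (length(candidates) == 0) stop("`candidates` must be nonempty")
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 1) return(candidates)

  n <- nrow(records)
  fold_id <- with_seed(derive_seed(seed, 77),
                       sample(rep_len(seq_len(folds), n)))
  col <- paste0(target, "_pct")

  val_rmse <- vapply(candidates, function(m) {
    sq_err <- unlist(lapply(seq_len(folds), function(f) {
      inner_train <- records[fold_id != f, , drop = FALSE]
      inner_val <- records[fold_id == f, , drop = FALSE]
      fit <- train_mlp(inner_train, target, n_hidden = m,
                       seed = derive_seed(seed, m * folds + f),
                       control = control, features = features)
      (inner_val[[col]] - mlp_predict(fit, inner_val))^2
    }))
    sqrt(mean(sq_err))
  }, numeric(1))

  chosen <- candidates[which.min(val_rmse)]
  attr(chosen, "validation") <- data.frame(n_hidden = candidates,
                                           val_rmse = val_rmse)
  chosen
}

#' Serialize an MLP surrogate to and from JSON
#'
#' Stores the architecture, weights, scalers and training state at full
#' double precision so a reloaded model reproduces predictions to
#' machine accuracy.
#'
#' @param model An `mlp_surrogate`.
#' @param path File path.
#' @return `write_mlp_json` returns the path invisibly; `read_mlp_json`
#'   the reloaded model.
#' @export
write_mlp_json <- function(model, path) {
  stopifnot(inherits(model, "mlp_surrogate"))
  payload <- list(
    n_hidden = nrow(model$W1), n_inputs = ncol(model$W1),
    W1 = model$W1, b1 = model$b1, w2 = model$w2, b0 = model$b0,
    target = model$target, features = model$features,
    x_scaler = scaler_payload(model$x_scaler),
    y_scaler = scaler_payload(model$y_scaler),
    state = model$state
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

scaler_payload <- function(s) {
  if (is.null(s)) NULL else list(lo = as.numeric(s$lo), hi = as.numeric(s$hi))
}

scaler_from_payload <- function(p) {
  if (is.null(p)) return(NULL)
  out <- list(lo = as.numeric(p$lo), hi = as.numeric(p$hi),
              width = as.numeric(p$hi) - as.numeric(p$lo))
  class(out) <- "range_scaler"
  out
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  state <- p$state
  if (!is.null(state$history)) state$history <- as.numeric(state$history)
  new_mlp(
    W1 = matrix(as.numeric(p$W1), nrow = p$n_hidden, ncol = p$n_inputs),
    b1 = as.numeric(p$b1), w2 = as.numeric(p$w2), b0 = as.numeric(p$b0),
    x_scaler = scaler_from_payload(p$x_scaler),
    y_scaler = scaler_from_payload(p$y_scaler),
    target = p$target, features = as.character(p$features), state = state
  )
}
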