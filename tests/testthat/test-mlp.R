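test_that("forward pass computes the three-layer map", {
  # all-zero weights: output is the bias through the identity output
  zero <- new_mlp(W1 = matrix(0, 2, 3), b1 = c(0, 0), w2 = c(0, 0), b0 = 0,
                  features = c("a", "b", "c"))
  expect_equal(mlp_predict(zero, c(1, 2, 3)), 0)
  # with an output scaler fitted on [0, 100], a zero net predicts the
  # range midpoint
  ysc <- scale_fit(matrix(c(0, 100), ncol = 1))
  zero_scaled <- new_mlp(matrix(0, 2, 3), c(0, 0), c(0, 0), 0,
                         y_scaler = ysc, features = c("a", "b", "c"))
  expect_equal(mlp_predict(zero_scaled, c(7, -1, 2)), 50)
  # hand-computable one-unit network, identity scalers
  hand <- new_mlp(matrix(1, 1, 1), 0, 2, 0.5, features = "x")
  expect_equal(mlp_predict(hand, 0), 0.5)
  expect_equal(mlp_predict(hand, 1), 2 * tanh(1) + 0.5)
  # deterministic
  m <- fixture_models()$cf
  x <- reconstruct_records(seed = 2)[1:5, ]
  expect_identical(mlp_predict(m, x), mlp_predict(m, x))
  expect_error(mlp_predict(hand, c(1, 2)), "length")
  expect_error(new_mlp(matrix(Inf, 1, 1), 0, 1, 0), "finite")
})

test_that("loss is the mean squared residual", {
  expect_equal(mlp_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mlp_loss(c(0, 0), c(3, 4)), 12.5)
  y <- runif(20)
  yhat <- runif(20)
  expect_equal(mlp_loss(3 * y, 3 * yhat), 9 * mlp_loss(y, yhat))
  expect_error(mlp_loss(numeric(0), numeric(0)), "empty")
  expect_error(mlp_loss(1:3, 1:2), "length")
})

test_that("fit metrics match hand-computed values", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 1)), 0.5)
  expect_equal(rmse(c(0, 1, 2), c(0, 1, 1)), sqrt(1 / 3))
  y <- runif(10)
  expect_equal(r_squared(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(r_squared(y, rep(mean(y), 10)), 0)
  expect_warning(r2 <- r_squared(rep(5, 4), 1:4), "zero-variance")
  expect_true(is.na(r2))
})

test_that("residual Jacobian matches central finite differences", {
  for (seed in 1:5) {
    m <- 3
    n <- 2
    k <- 6
    n_par <- m * (n + 2) + 1
    theta <- sterilopt:::with_seed(seed, runif(n_par, -1, 1))
    Xs <- sterilopt:::with_seed(seed + 100,
                                matrix(runif(k * n, -1, 1), ncol = n))
    fw <- sterilopt:::mlp_forward_scaled(theta, m, n, Xs)
    jac <- sterilopt:::mlp_jacobian(theta, m, n, Xs, fw$Z)
    h <- 1e-6
    fd <- sapply(seq_len(n_par), function(p) {
      up <- theta; up[p] <- up[p] + h
      dn <- theta; dn[p] <- dn[p] - h
      (sterilopt:::mlp_forward_scaled(up, m, n, Xs)$yhat -
         sterilopt:::mlp_forward_scaled(dn, m, n, Xs)$yhat) / (2 * h)
    })
    expect_lt(max(abs(jac - fd)) / max(abs(jac)), 1e-5)
  }
})

test_that("training recovers a realizable teacher to near-zero loss", {
  rec <- teacher_records()
  fit <- train_mlp(rec, "cf", n_hidden = 1, seed = 2,
                   control = lm_control(n_starts = 4, val_frac = 0),
                   features = "x")
  expect_lt(mlp_loss(rec$cf_pct, mlp_predict(fit, rec)), 1e-6)
})

test_that("a constant target trains to a constant predictor", {
  rec <- teacher_records()
  rec$cf_pct <- 42
  fit <- suppressWarnings(
    train_mlp(rec, "cf", n_hidden = 2, seed = 1, control = fast_ctl(),
              features = "x")
  )
  expect_lt(max(abs(mlp_predict(fit, rec) - 42)), 1e-6)
})

test_that("accepted-step loss history is monotone non-increasing", {
  rec <- teacher2_records(noise_sd = 0.05)
  for (ctl in list(fast_ctl(), lm_control(n_starts = 1, max_epochs = 150))) {
    fit <- train_mlp(rec, "cf", n_hidden = 3, seed = 4, control = ctl,
                     features = "x")
    expect_false(is.unsorted(rev(fit$state$history)))
    expect_gt(length(fit$state$history), 1)
  }
})

test_that("training is reproducible from the seed", {
  rec <- teacher2_records()
  f1 <- train_mlp(rec, "cf", n_hidden = 2, seed = 7, control = fast_ctl(),
                  features = "x")
  f2 <- train_mlp(rec, "cf", n_hidden = 2, seed = 7, control = fast_ctl(),
                  features = "x")
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$state$history, f2$state$history)
  expect_error(train_mlp(rec[1, ], "cf", features = "x"), "distinct")
  expect_error(train_mlp(rec, "cf", n_hidden = 0, features = "x"),
               "n_hidden")
})

test_that("architecture search rejects an undersized network", {
  rec <- teacher2_records()
  chosen <- select_architecture(rec, "cf", candidates = c(1, 2, 8), seed = 3,
                                control = fast_ctl(), features = "x")
  v <- attr(chosen, "validation")
  expect_gt(v$val_rmse[v$n_hidden == 1], min(v$val_rmse[v$n_hidden >= 2]))
  expect_true(as.integer(chosen) >= 2)
  # a single candidate is returned unconditionally
  expect_equal(select_architecture(rec, "cf", candidates = 5), 5L)
  expect_error(select_architecture(rec, "cf", candidates = integer(0)),
               "nonempty")
})

test_that("evaluation reports both phases on unclipped predictions", {
  rec <- reconstruct_records(seed = 6)
  sp <- split_train_test(rec, seed = 6)
  met <- evaluate_mlp(fixture_models()$cf, sp)
  expect_equal(met$phase, c("train", "test"))
  expect_equal(met$n, c(165, 54))
  expect_true(all(met$rmse >= 0))
  expect_true(all(met$r2 <= 1))
})

test_that("predictions on the reconstructed data stay in a sane band", {
  rec <- reconstruct_records(seed = 8)
  for (m in fixture_models()) {
    p <- mlp_predict(m, rec)
    expect_true(all(p > -20 & p < 120))
  }
})

test_that("models reload from JSON to machine precision", {
  m <- fixture_models()$ev
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp_json(m, path)
  back <- read_mlp_json(path)
  rec <- reconstruct_records(seed = 2)[1:20, ]
  expect_equal(mlp_predict(back, rec), mlp_predict(m, rec),
               tolerance = 1e-12)
  expect_equal(back$W1, m$W1, tolerance = 1e-12)
  expect_equal(back$state$E, m$state$E, tolerance = 1e-12)
})
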