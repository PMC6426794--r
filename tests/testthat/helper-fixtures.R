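# Shared fixtures, all generated in code.

# Report every expectation; never abort the run at a failure budget.
options(testthat.progress.max_fails = 1000)

# Brute-force non-dominated sorting by repeated peeling with pairwise
# dominance checks; the O(N^2 * fronts) oracle for the fast sort.
bf_sort_ranks <- function(obj) {
  n <- nrow(obj)
  ranks <- integer(n)
  alive <- rep(TRUE, n)
  r <- 0
  while (any(alive)) {
    r <- r + 1
    idx <- which(alive)
    nd <- vapply(idx, function(i) {
      !any(vapply(idx, function(j) {
        j != i && dominates(obj[j, ], obj[i, ])
      }, logical(1)))
    }, logical(1))
    ranks[idx[nd]] <- r
    alive[idx[nd]] <- FALSE
  }
  ranks
}

# Noiseless single-input teacher dataset: y = 0.8 * tanh(x), the target
# realizable by a one-hidden-unit network.
teacher_records <- function(n = 50, seed = 11) {
  x <- sterilopt:::with_seed(seed, stats::runif(n, -2, 2))
  data.frame(x = x, cf_pct = 0.8 * tanh(x))
}

# Records from a known two-hidden-unit teacher network over one input.
teacher2_records <- function(n = 120, seed = 12, noise_sd = 0.01) {
  sterilopt:::with_seed(seed, {
    x <- stats::runif(n, -3, 3)
    y <- 1.5 * tanh(2 * x - 1) - 0.8 * tanh(x + 2) +
      stats::rnorm(n, sd = noise_sd)
    data.frame(x = x, cf_pct = y)
  })
}

# Tiny toy records over the real seven-input layout: the response
# depends only on immersion time, one sterilant column carries pure
# noise and the remaining five are constant zero.
toy_sensitivity_records <- function(n = 150, seed = 13) {
  sterilopt:::with_seed(seed, {
    rec <- data.frame(
      treatment_id = paste0("t", seq_len(n)),
      replicate = 1L
    )
    for (col in sterilopt:::input_names()) rec[[col]] <- 0
    rec$time_min <- stats::runif(n, 2, 15)
    rec$naocl_pct <- stats::runif(n, 0, 2)          # pure noise input
    rec$cf_pct <- 10 + 5 * rec$time_min + stats::rnorm(n, sd = 2)
    rec$ev_pct <- 50
    rec
  })
}

# Fast LM settings for small fixtures.
fast_ctl <- function(...) {
  lm_control(n_starts = 2, max_epochs = 200, val_frac = 0, ...)
}

# Trained surrogates on noiseless reconstructed records, computed once
# per test session (stable, fast, deterministic).
fixture_env <- new.env(parent = emptyenv())

fixture_models <- function() {
  if (is.null(fixture_env$models)) {
    rec <- reconstruct_records(noise_scale = 0, seed = 1)
    fixture_env$models <- list(
      cf = train_mlp(rec, "cf", n_hidden = 7, seed = 5, control = fast_ctl()),
      ev = train_mlp(rec, "ev", n_hidden = 7, seed = 6, control = fast_ctl())
    )
  }
  fixture_env$models
}
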