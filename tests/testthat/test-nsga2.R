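test_that("pareto dominance follows the minimization convention", {
  # published compromise pairs as (CF, -EV): the NaOCl protocol
  # dominates the mercuric chloride one
  expect_true(dominates(c(0, -99.98), c(14.58, -68.65)))
  expect_false(dominates(c(14.58, -68.65), c(0, -99.98)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_false(dominates(c(1, 0), c(0, 1)))
  expect_false(dominates(c(0, 1), c(1, 0)))
  expect_true(dominates(c(0, 0), c(0, 1)))
})

test_that("fast non-dominated sort partitions into correct fronts", {
  one <- fast_non_dominated_sort(matrix(c(3, 4), 1))
  expect_equal(one$ranks, 1L)
  # strictly dominated chain: four singleton fronts
  chain <- matrix(c(1, 1, 2, 2, 3, 3, 4, 4), ncol = 2, byrow = TRUE)
  res <- fast_non_dominated_sort(chain)
  expect_equal(res$ranks, 1:4)
  expect_length(res$fronts, 4)
  # random instances against the brute-force oracle
  for (seed in 1:10) {
    obj <- sterilopt:::with_seed(seed, matrix(runif(2 * 40), ncol = 2))
    expect_equal(fast_non_dominated_sort(obj)$ranks, bf_sort_ranks(obj))
  }
})

test_that("crowding distance matches hand computation", {
  expect_equal(crowding_distance(matrix(c(1, 2), 1)), Inf)
  expect_equal(crowding_distance(matrix(c(0, 1, 1, 0), 2)), c(Inf, Inf))
  three <- matrix(c(0, 4,
                    1, 1,
                    4, 0), ncol = 2, byrow = TRUE)
  expect_equal(crowding_distance(three), c(Inf, 2, Inf))
  # duplicated interior objective vectors get zero distance
  dup <- matrix(c(0, 4,
                  1, 1,
                  1, 1,
                  4, 0), ncol = 2, byrow = TRUE)
  d <- crowding_distance(dup)
  expect_equal(d[2:3], c(0, 0))
  # a zero-range objective contributes nothing
  flat <- matrix(c(0, 5,
                   1, 5,
                   2, 5), ncol = 2, byrow = TRUE)
  expect_equal(crowding_distance(flat), c(Inf, 1, Inf))
})

test_that("binary tournament prefers rank then crowding", {
  # deterministic comparator under the hood
  expect_equal(sterilopt:::crowded_better(1, 2, c(1, 3), c(0, 9)), 1)
  expect_equal(sterilopt:::crowded_better(1, 2, c(2, 2), c(Inf, 0.4)), 1)
  expect_equal(sterilopt:::crowded_better(1, 2, c(2, 2), c(0.4, Inf)), 2)
  expect_equal(sterilopt:::crowded_better(1, 2, c(2, 2), c(1, 1)), 1)
  # identical individuals: selection is uniform (chi-square sanity)
  n <- 8
  draws <- sterilopt:::with_seed(99, replicate(10000, tournament_select(
    rep(1L, n), rep(0, n))))
  tab <- table(factor(draws, levels = 1:n))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("variation operators respect bounds and their limits", {
  lower <- c(0, 5)
  upper <- c(2, 15)
  p1 <- c(0.5, 7)
  p2 <- c(1.5, 12)
  # no crossover, no mutation: children are the parents
  sterilopt:::with_seed(1, {
    kids <- sbx_crossover(p1, p2, eta = 15, p_c = 0, lower, upper)
    expect_equal(kids[[1]], p1)
    expect_equal(kids[[2]], p2)
    expect_equal(polynomial_mutation(p1, p_m = 0, lower = lower,
                                     upper = upper), p1)
  })
  # distribution-index limit: children converge to parents
  sterilopt:::with_seed(2, {
    kids <- sbx_crossover(p1, p2, eta = 1e6, p_c = 1, lower, upper)
    expect_lt(max(abs(kids[[1]] - p1)), 1e-3)
    expect_lt(max(abs(kids[[2]] - p2)), 1e-3)
  })
  # offspring always within bounds
  sterilopt:::with_seed(3, {
    for (i in 1:2500) {
      kids <- sbx_crossover(p1, p2, 15, 0.9, lower, upper)
      child <- polynomial_mutation(kids[[sample(2, 1)]], 20, 0.5,
                                   lower, upper)
      if (any(child < lower) || any(child > upper)) {
        fail(sprintf("offspring out of bounds: (%g, %g)",
                     child[1], child[2]))
      }
    }
    succeed()
  })
})

test_that("the generational loop is elitist and reproducible", {
  sphere <- function(d) cbind(d[, 1]^2 + d[, 2]^2, (d[, 1] - 1)^2)
  cfg <- nsga_config(population_size = 40, generations = 25, seed = 4)
  res <- nsga2_evolve(sphere, c(-2, -2), c(2, 2), cfg)
  # archive hypervolume never decreases
  expect_false(is.unsorted(res$hv_history))
  # final front is pairwise non-dominated
  for (i in seq_len(nrow(res$objectives))) {
    for (j in seq_len(nrow(res$objectives))) {
      if (i != j) {
        expect_false(dominates(res$objectives[i, ], res$objectives[j, ]))
      }
    }
  }
  # reproducible from the seed
  res2 <- nsga2_evolve(sphere, c(-2, -2), c(2, 2), cfg)
  expect_identical(res$decisions, res2$decisions)
  # constant objectives: everyone is rank 1
  const <- nsga2_evolve(function(d) cbind(rep(1, nrow(d)), rep(2, nrow(d))),
                        c(0, 0), c(1, 1),
                        nsga_config(population_size = 20, generations = 3,
                                    seed = 1))
  expect_equal(nrow(const$decisions), 20)
  # non-finite objectives are reported with the decision
  expect_error(
    nsga2_evolve(function(d) cbind(rep(NaN, nrow(d)), rep(1, nrow(d))),
                 c(0, 0), c(1, 1),
                 nsga_config(population_size = 4, generations = 1, seed = 1)),
    "non-finite"
  )
})

test_that("surrogate objectives embed the decision into the input layout", {
  models <- fixture_models()
  fn <- make_objectives(models$cf, models$ev, "NaOCl")
  # zero dose at the control time predicts total contamination
  ctrl <- fn(c(0, 10))
  expect_lt(abs(ctrl[1, 1] - 100), 5)
  # objectives clipped: CF in [0, 100], internal EV component in [-100, 0]
  grid <- as.matrix(expand.grid(seq(0, 2, length = 15),
                                seq(5, 15, length = 15)))
  obj <- fn(grid)
  expect_true(all(obj[, 1] >= 0 & obj[, 1] <= 100))
  expect_true(all(obj[, 2] >= -100 & obj[, 2] <= 0))
  # deterministic
  expect_identical(fn(c(1.5, 12)), fn(c(1.5, 12)))
  expect_error(make_objectives(models$cf, models$ev, "vinegar"))
})

test_that("the front trades contamination against viability monotonically", {
  models <- fixture_models()
  opt <- optimize_experiment(models$cf, models$ev, "NaOCl",
                             nsga_config(population_size = 40,
                                         generations = 30, seed = 2))
  # on a two-objective front, giving up contamination control must buy
  # viability: sorted by ascending CF, EV is non-decreasing
  front <- opt$front
  expect_false(is.unsorted(front$ev_pred))
  expect_true(all(front$concentration >= 0 & front$concentration <= 2))
  expect_true(all(front$time_min >= 5 & front$time_min <= 15))
})
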