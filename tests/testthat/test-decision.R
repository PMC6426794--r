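test_that("ideal-point references come from observed extremes", {
  rec <- reconstruct_records(seed = 1)
  refs <- compute_refs(rec)
  expect_equal(refs$cf_ref, 0)
  expect_equal(refs$ev_ref, 100)
  one <- data.frame(cf_pct = 40, ev_pct = 60)
  expect_equal(compute_refs(one), list(cf_ref = 40, ev_ref = 60))
  expect_equal(compute_refs(rbind(one, one, one)),
               compute_refs(one))
  expect_error(compute_refs(one[0, ]), "empty")
})

test_that("compromise selection minimizes squared ideal-point distance", {
  front <- data.frame(
    concentration = c(1.6, 1.9),
    time_min = c(14, 15),
    cf_pred = c(0, 5),
    ev_pred = c(99.98, 100)
  )
  sel <- select_ideal(front, list(cf_ref = 0, ev_ref = 100))
  expect_equal(sel$cf_pred, 0)
  expect_equal(sel$ideal_distance2, 0.02^2)
  # singleton front returns its member; exact hit has distance 0
  single <- front[2, ]
  expect_equal(select_ideal(single)$cf_pred, 5)
  hit <- data.frame(concentration = 1, time_min = 10,
                    cf_pred = 0, ev_pred = 100)
  expect_equal(select_ideal(hit)$ideal_distance2, 0)
  expect_error(select_ideal(front[0, ]), "empty")
})

test_that("selection is invariant to front ordering and breaks ties", {
  front <- data.frame(
    concentration = c(1, 2, 3, 4),
    time_min = c(12, 8, 10, 8),
    cf_pred = c(3, 0, 4, 0),
    ev_pred = c(96, 96, 95, 96)
  )
  sel <- select_ideal(front)
  for (seed in 1:5) {
    perm <- sterilopt:::with_seed(seed, sample(nrow(front)))
    sel_p <- select_ideal(front[perm, ])
    expect_equal(sel_p$concentration, sel$concentration)
  }
  # rows 2 and 4 tie on distance and CF; the shorter time wins
  expect_equal(sel$time_min, 8)
  expect_equal(sel$cf_pred, 0)
  expect_equal(sel$concentration, 2)
})

test_that("select_ideal accepts a raw pareto_front object", {
  sphere <- function(d) cbind(d[, 1]^2, (d[, 1] - 1)^2)
  res <- nsga2_evolve(sphere, c(-1, 0), c(2, 1),
                      nsga_config(population_size = 20, generations = 10,
                                  seed = 3))
  sel <- select_ideal(res, list(cf_ref = 0, ev_ref = 0))
  expect_true(all(c("cf_pred", "ev_pred", "ideal_distance2") %in% names(sel)))
})

test_that("sensitivity ranking finds the informative input", {
  rec <- toy_sensitivity_records()
  split <- split_train_test(rec, fraction = 0.75, seed = 2)
  rep <- variable_sensitivity(split, "cf", n_hidden = 2, seed = 3,
                              control = lm_control(n_starts = 3, max_epochs = 300,
                                                   val_frac = 0))
  expect_s3_class(rep, "sensitivity_report")
  expect_setequal(rep$rank, 1:7)
  expect_true(all(rep$vsr >= 0))
  # the response is a function of immersion time alone
  expect_equal(rep$rank[rep$input == "time_min"], 1L)
  expect_gt(rep$vsr[rep$input == "time_min"],
            rep$vsr[rep$input == "naocl_pct"])
  # constant inputs cannot change the attainable fit
  const_vsr <- rep$vsr[!(rep$input %in% c("time_min", "naocl_pct"))]
  expect_true(all(abs(const_vsr - 1) < 0.1))
  # rank ordering matches descending VSR
  expect_equal(order(-rep$vsr), order(rep$rank))
})

test_that("sensitivity reports export as CSV", {
  rec <- toy_sensitivity_records()
  split <- split_train_test(rec, fraction = 0.75, seed = 2)
  rep <- variable_sensitivity(split, "cf", n_hidden = 2, seed = 3,
                              control = lm_control(n_starts = 3, max_epochs = 300,
                                                   val_frac = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_csv(rep, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("output", "input", "vse", "vsr", "rank"))
  expect_equal(nrow(back), 7)
  expect_equal(unique(back$output), "CF")
})
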