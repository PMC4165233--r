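test_that("mann_whitney matches the textbook example", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
})

test_that("mann_whitney warns and reports p = 1 on degenerate samples", {
  expect_warning(res <- mann_whitney(rep(5, 4), rep(5, 3)), "degenerate")
  expect_equal(res$p_value, 1)
  expect_equal(res$method, "degenerate")
})

test_that("near-identical samples are far from significance", {
  x <- c(1, 2, 3, 4, 5)
  res <- mann_whitney(x, x + 0.0001)
  expect_gt(res$p_value, 0.5)
  expect_equal(res$p_value, mw_enum_p(x, x + 0.0001), tolerance = 1e-12)
})

test_that("mann_whitney rejects empty samples and falls back on ties", {
  expect_error(mann_whitney(numeric(), 1:3),
               class = "dendrofire_argument_error")
  res <- mann_whitney(c(1, 2, 2), c(2, 3, 4))
  expect_equal(res$method, "normal approximation")
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("exact p equals full enumeration on random tie-free samples", {
  local_seed(99, {
    for (i in 1:40) {
      n <- sample(2:7, 1); m <- sample(2:7, 1)
      v <- sample(1000, n + m) + runif(n + m)  # tie-free
      x <- v[seq_len(n)]; y <- v[-seq_len(n)]
      expect_equal(mann_whitney(x, y)$p_value, mw_enum_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("bayes classifier separates trivially separable classes", {
  model <- bayes_train(c(0, 0.1, -0.1, 10, 10.1, 9.9),
                       c("RS", "RS", "RS", "IB", "IB", "IB"))
  expect_equal(bayes_predict(model, 1), "RS")
  expect_equal(bayes_predict(model, 9), "IB")
  expect_equal(bayes_predict(model, c(-1, 11)), c("RS", "IB"))
})

test_that("exact posterior ties go to IB", {
  # symmetric classes around 5: the midpoint has equal likelihood
  model <- bayes_train(c(0, 1, 9, 10), c("RS", "RS", "IB", "IB"))
  expect_equal(bayes_predict(model, 5), "IB")
})

test_that("bayes_train validates labels", {
  expect_error(bayes_train(1:4, c("RS", "RS", "XX", "IB")),
               class = "dendrofire_argument_error")
  expect_error(bayes_train(1:4, rep("RS", 4)),
               class = "dendrofire_value_error")
  expect_error(bayes_train(1:4, c("RS", "IB")),
               class = "dendrofire_argument_error")
})

test_that("a constant training class still yields a proper density", {
  model <- bayes_train(c(5, 5, 5, 8, 9, 10),
                       c("RS", "RS", "RS", "IB", "IB", "IB"))
  expect_equal(bayes_predict(model, 5), "RS")
  expect_equal(bayes_predict(model, 9), "IB")
})

test_that("density estimation never touches test observations", {
  local_seed(4, {
    x <- c(rnorm(20), rnorm(20, 3))
    labels <- rep(c("RS", "IB"), each = 20)
    train <- c(1:16, 21:36)
    m1 <- bayes_train(x[train], labels[train])
    # shuffling the held-out labels cannot change the trained model
    labels2 <- labels
    labels2[-train] <- sample(labels[-train])
    m2 <- bayes_train(x[train], labels2[train])
    expect_identical(m1, m2)
  })
})

test_that("bayes_evaluate balances, splits and reports in range", {
  local_seed(11, {
    x <- c(rnorm(30, 0), rnorm(12, 4))
    labels <- c(rep("RS", 30), rep("IB", 12))
  })
  rep <- bayes_evaluate(x, labels, n_repeats = 6, seed = 7)
  expect_s3_class(rep, "classifier_report")
  # balanced to the minority class size
  expect_equal(rep$summary$n_per_class, 12L)
  expect_equal(nrow(rep$repeats), 6L)
  metrics <- unlist(rep$repeats[, c("sensitivity", "specificity",
                                    "accuracy")])
  expect_true(all(metrics >= 0 & metrics <= 1))
  expect_equal(rep$positive_class, "IB")
  # deterministic under the same master seed
  rep2 <- bayes_evaluate(x, labels, n_repeats = 6, seed = 7)
  expect_identical(rep$repeats, rep2$repeats)
  # different seed gives different resamples
  rep3 <- bayes_evaluate(x, labels, n_repeats = 6, seed = 8)
  expect_false(identical(rep$repeats$seed, rep3$repeats$seed))
})

test_that("perfectly separated classes score accuracy 1 every repeat", {
  x <- c(1:15, 101:115)
  labels <- rep(c("RS", "IB"), each = 15)
  rep <- bayes_evaluate(x, labels, n_repeats = 5, seed = 3)
  expect_true(all(rep$repeats$accuracy == 1))
  expect_equal(rep$summary$accuracy, 1)
})

test_that("bayes_evaluate rejects unusable inputs", {
  expect_error(bayes_evaluate(1:3, c("RS", "RS", "IB")),
               class = "dendrofire_value_error")
  expect_error(bayes_evaluate(1:8, rep(c("RS", "IB"), 4),
                              train_frac = 0.01),
               class = "dendrofire_value_error")
})

test_that("classifier_report tidiers work", {
  x <- c(rnorm(10), rnorm(10, 5))
  labels <- rep(c("RS", "IB"), each = 10)
  rep <- bayes_evaluate(x, labels, n_repeats = 3, seed = 1)
  expect_equal(nrow(tidy(rep)), 3L)
  expect_equal(nrow(glance(rep)), 1L)
  expect_true(all(c("sensitivity", "specificity", "accuracy") %in%
                    names(glance(rep))))
})

test_that("basal_profile applies the strict majority rule", {
  grid <- tibble::tibble(
    basal_id = rep(c("b1", "b2", "b3", "b4"), each = 2),
    apical_id = rep(c("a1", "a2"), 4),
    category = c("RS", "RS",   # b1: RS
                 "RS", "IB",   # b2: split -> IB (not > half)
                 "IB", "Q",    # b3: IB
                 "RS", "RS"),  # b4: second row fails below
    error = c(rep(NA_character_, 7), "boom"))
  prof <- basal_profile(grid)
  expect_equal(prof$profile[prof$basal_id == "b1"], "RS")
  expect_equal(prof$profile[prof$basal_id == "b2"], "IB")
  expect_equal(prof$profile[prof$basal_id == "b3"], "IB")
  # failed combination drops from the denominator: 1 RS of 1 -> RS
  expect_equal(prof$n_total[prof$basal_id == "b4"], 1L)
  expect_equal(prof$profile[prof$basal_id == "b4"], "RS")
  all_failed <- tibble::tibble(basal_id = "b1", apical_id = "a1",
                               category = NA_character_, error = "boom")
  expect_error(basal_profile(all_failed), class = "dendrofire_value_error")
})

test_that("feature_correlation matches hand oracles and flags", {
  ft <- tibble::tibble(total_length_um = c(1, 2, 3, 4),
                       volume_um3 = c(2, 4, 6, 8),
                       branch_number = c(5, 5, 5, 5))
  expect_warning(res <- feature_correlation(ft), "zero-variance")
  r_lv <- res$r[res$feature_a == "total_length_um" &
                  res$feature_b == "volume_um3"]
  expect_equal(r_lv, 1)
  expect_true(all(is.na(res$r[!res$defined])))
  expect_error(feature_correlation(ft[1:2, ]),
               class = "dendrofire_value_error")
  expect_error(feature_correlation(ft, columns = c("nope", "volume_um3")),
               class = "dendrofire_argument_error")
})

test_that("independent noise correlates near zero", {
  local_seed(12, {
    ft <- tibble::tibble(total_length_um = rnorm(1000),
                         volume_um3 = rnorm(1000),
                         branch_number = rnorm(1000))
  })
  res <- feature_correlation(ft)
  expect_true(all(abs(res$r) < 0.1))
})

test_that("run_grid isolates per-cell failures", {
  fx <- fixture_suite()
  # apical-only morphology as a basal donor: graft fails for that row only
  basal_set <- list(ok = fx$y_tree, broken = fx$apical_simple)
  grid <- run_grid(basal_set, list(a1 = fx$apical_simple),
                   control = graft(fx$soma_only, fx$y_tree,
                                   fx$apical_simple))
  expect_s3_class(grid, "grid_result")
  expect_equal(nrow(grid), 2L)
  ok_row <- grid[grid$basal_id == "ok", ]
  expect_true(is.na(ok_row$error))
  expect_true(ok_row$category %in% c("RS", "IB", "Q"))
  bad_row <- grid[grid$basal_id == "broken", ]
  expect_false(is.na(bad_row$error))
  expect_true(is.na(bad_row$category))
  g <- glance(grid)
  expect_equal(g$n_failed, 1L)
  expect_gt(attr(grid, "rin_control"), 0)
  expect_equal(tidy(grid)$basal_id, c("ok", "broken"))
})

test_that("run_grid validates inputs", {
  fx <- fixture_suite()
  expect_error(run_grid(list(), list(a = fx$apical_simple)),
               class = "dendrofire_argument_error")
})
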