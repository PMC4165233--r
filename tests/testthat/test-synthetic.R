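test_that("tree_recipe validates its parameters", {
  expect_error(tree_recipe(n_stems = 0), class = "dendrofire_argument_error")
  expect_error(tree_recipe(bif_prob = 1.2),
               class = "dendrofire_argument_error")
  expect_error(tree_recipe(seg_length_mean = -5),
               class = "dendrofire_argument_error")
  expect_error(tree_recipe(taper = 0), class = "dendrofire_argument_error")
  expect_error(tree_recipe(max_segments = 0),
               class = "dendrofire_argument_error")
})

test_that("generated trees are valid morphologies", {
  for (seed in c(1, 42, 360)) {
    m <- generate_tree(tree_recipe(seed = seed))
    expect_s3_class(m, "morphology")  # construction validates
    expect_true(all(m$points$radius > 0))
    expect_true(any(m$points$structure == 3L))
  }
  ap <- generate_tree(tree_recipe(tree = "apical", seed = 5))
  expect_true(any(ap$points$structure == 4L))
  expect_false(any(ap$points$structure == 3L))
})

test_that("the same seed yields a byte-identical SWC file", {
  r <- tree_recipe(seed = 77)
  p1 <- withr::local_tempfile(fileext = ".swc")
  p2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(generate_tree(r), p1)
  write_swc(generate_tree(r), p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed yields a different tree
  m3 <- generate_tree(tree_recipe(seed = 78))
  expect_false(identical(m3$points, generate_tree(r)$points))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(3)
  set.seed(123)
  invisible(generate_tree(tree_recipe(seed = 9)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("zero bifurcation probability gives unbranched stems", {
  m <- generate_tree(tree_recipe(n_stems = 6, bif_prob = 0, seed = 3))
  expect_equal(branch_number(m), 6L)
  sec <- sections(m)
  expect_equal(sum(sec$is_tip[sec$structure == 3L]), 6L)
})

test_that("realized segment lengths track the recipe mean", {
  lens <- purrr::map_dbl(1:100, function(s) {
    m <- generate_tree(tree_recipe(n_stems = 2, bif_prob = 0,
                                   seg_length_mean = 60,
                                   seg_length_sd = 10, max_segments = 3,
                                   seed = s))
    total_length(m) / 6  # 2 stems x 3 segments
  })
  expect_lt(abs(mean(lens) - 60) / 60, 0.1)
})

test_that("population generation is deterministic with ground truth", {
  r <- population_recipe(n_per_class = 4, seed = 12)
  pop1 <- generate_population(r)
  pop2 <- generate_population(r)
  expect_equal(length(pop1$morphologies), 8L)
  expect_equal(pop1$labels$class, rep(c("RS", "IB"), each = 4))
  expect_equal(names(pop1$morphologies), pop1$labels$id)
  for (id in pop1$labels$id) {
    expect_identical(pop1$morphologies[[id]]$points,
                     pop2$morphologies[[id]]$points)
  }
  expect_error(population_recipe(n_per_class = 0),
               class = "dendrofire_argument_error")
})

test_that("realized class medians follow the recipe direction", {
  pop <- generate_population(population_recipe(n_per_class = 12, seed = 7))
  ft <- morpho_features(pop$morphologies)
  ft$class <- pop$labels$class[match(ft$file, pop$labels$id)]
  med <- function(col, cl) median(ft[[col]][ft$class == cl])
  expect_gt(med("total_length_um", "RS"), med("total_length_um", "IB"))
  expect_gt(med("branch_number", "RS"), med("branch_number", "IB"))
  expect_gt(med("median_diameter_um", "RS"), med("median_diameter_um", "IB"))
  # the separation is statistically detectable
  mw <- mann_whitney(ft$total_length_um[ft$class == "RS"],
                     ft$total_length_um[ft$class == "IB"])
  expect_lt(mw$p_value, 0.05)
})

test_that("fixture_suite ships the documented morphologies", {
  fx <- fixture_suite()
  expect_setequal(names(fx),
                  c("soma_only", "stick", "cable", "y_tree", "basal3",
                    "basal_control", "apical_complex", "apical_simple"))
  expect_equal(nrow(fx$soma_only$points), 1L)
  expect_equal(mep(fx$stick), 1, tolerance = 1e-9)
  expect_equal(branch_number(fx$y_tree), 3L)
  expect_gt(total_length(fx$apical_complex, "apical"),
            total_length(fx$apical_simple, "apical"))
  expect_gt(branch_number(fx$apical_complex, "apical"),
            branch_number(fx$apical_simple, "apical"))
  # the analytic cable has no soma
  expect_false(any(fx$cable$points$structure == 1L))
})

test_that("basal_load_ladder is ordered by total length", {
  ladder <- basal_load_ladder(n_steps = 4)
  lens <- purrr::map_dbl(ladder, total_length)
  expect_true(all(diff(lens) > 0))
  expect_equal(lens, 250 * (1:4), tolerance = 1e-9)
  expect_equal(purrr::map_int(ladder, branch_number), 1:4)
  expect_error(basal_load_ladder(n_steps = 0),
               class = "dendrofire_argument_error")
})
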