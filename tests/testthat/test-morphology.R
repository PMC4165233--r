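test_that("as_morphology validates its point table", {
  good <- tibble::tibble(id = 1:2, structure = c(1L, 3L),
                         x = c(0, 10), y = 0, z = 0, radius = c(8, 1),
                         parent_id = c(-1L, 1L))
  expect_s3_class(as_morphology(good), "morphology")

  expect_error(as_morphology(good[0, ]), class = "dendrofire_validation_error")
  bad <- good; bad$radius[2] <- 0
  expect_error(as_morphology(bad), class = "dendrofire_validation_error")
  bad <- good; bad$structure[2] <- 9L
  expect_error(as_morphology(bad), class = "dendrofire_validation_error")
  bad <- good; bad$id[2] <- 1L
  expect_error(as_morphology(bad), class = "dendrofire_validation_error")
  bad <- good; bad$parent_id[2] <- -1L  # two roots
  expect_error(as_morphology(bad), class = "dendrofire_validation_error")
  bad <- good; bad$parent_id[2] <- 5L  # missing parent
  expect_error(as_morphology(bad), class = "dendrofire_structural_error")
  bad <- good; bad$parent_id[2] <- 2L  # self-parent / not sorted
  expect_error(as_morphology(bad), class = "dendrofire_structural_error")
  expect_error(as_morphology(good[, 1:5]),
               class = "dendrofire_validation_error")
})

test_that("SWC files round-trip losslessly", {
  fx <- fixture_suite()
  for (m in list(fx$y_tree, fx$basal3, fx$apical_complex)) {
    path <- withr::local_tempfile(fileext = ".swc")
    write_swc(m, path)
    m2 <- read_swc(path)
    expect_equal(m2$points, m$points)
  }
})

test_that("read_swc rejects malformed input cleanly", {
  p <- withr::local_tempfile(fileext = ".swc")
  expect_error(read_swc(file.path(tempdir(), "nope.swc")),
               class = "dendrofire_io_error")
  writeLines(c("# only comments"), p)
  expect_error(read_swc(p), class = "dendrofire_validation_error")
  writeLines("1 1 0 0 0 8", p)  # 6 columns
  expect_error(read_swc(p), class = "dendrofire_validation_error")
  writeLines("1 1 0 0 zero 8 -1", p)
  expect_error(read_swc(p), class = "dendrofire_validation_error")
})

test_that("sections partition covers every non-root point exactly once", {
  for (seed in c(3, 14, 27)) {
    m <- random_test_tree(seed)
    sec <- sections(m)
    covered <- unlist(purrr::map(sec$point_ids, function(ids) ids[-1L]))
    root <- m$points$id[m$points$parent_id == -1L]
    expect_setequal(covered, setdiff(m$points$id, root))
    expect_false(anyDuplicated(covered) > 0)
    # section lengths sum to the sum of all inter-point distances
    pts <- m$points
    rows <- match(pts$parent_id, pts$id)
    ok <- !is.na(rows)
    d <- sqrt((pts$x[ok] - pts$x[rows[ok]])^2 +
                (pts$y[ok] - pts$y[rows[ok]])^2 +
                (pts$z[ok] - pts$z[rows[ok]])^2)
    expect_equal(sum(sec$length), sum(d), tolerance = 1e-12)
  }
})

test_that("y_tree fixture has the expected section structure", {
  sec <- sections(fixture_suite()$y_tree)
  basal <- sec[sec$structure == 3L, ]
  expect_equal(nrow(basal), 3L)  # stem + 2 daughter branches
  expect_equal(sum(basal$is_tip), 2L)
})

test_that("graft conserves donor-tree morphometrics exactly", {
  fx <- fixture_suite()
  g <- graft(fx$soma_only, fx$basal3, fx$apical_simple)
  expect_equal(total_length(g, "basal"), total_length(fx$basal3, "basal"))
  expect_equal(tree_volume(g, "basal"), tree_volume(fx$basal3, "basal"))
  expect_equal(branch_number(g, "basal"), branch_number(fx$basal3, "basal"))
  expect_equal(mep(g, "basal"), mep(fx$basal3, "basal"))
  expect_equal(total_length(g, "apical"),
               total_length(fx$apical_simple, "apical"))
  expect_equal(mep(g, "apical"), mep(fx$apical_simple, "apical"))
  # ids renumbered consecutively from 1
  expect_equal(g$points$id, seq_len(nrow(g$points)))
})

test_that("graft validates its donors", {
  fx <- fixture_suite()
  expect_error(graft(fx$soma_only, fx$apical_simple, fx$apical_simple),
               class = "dendrofire_graft_error")
  expect_error(graft(fx$soma_only, fx$basal3, fx$basal3),
               class = "dendrofire_graft_error")
  expect_error(graft(fx$cable, fx$basal3, fx$apical_simple),
               class = "dendrofire_graft_error")
})

test_that("split_section preserves geometry and adds a boundary", {
  m <- fixture_suite()$y_tree
  sec <- sections(m)
  target <- sec$section_id[sec$structure == 3L][1L]
  m2 <- split_section(m, target, 0.37)
  expect_equal(nrow(m2$points), nrow(m$points) + 1L)
  expect_equal(nrow(sections(m2)), nrow(sec) + 1L)
  expect_equal(total_length(m2), total_length(m), tolerance = 1e-12)
  # topological branch count ignores the split
  expect_equal(branch_number(m2), branch_number(m))
})

test_that("split_section rejects bad arguments", {
  m <- fixture_suite()$y_tree
  expect_error(split_section(m, 1, 0), class = "dendrofire_argument_error")
  expect_error(split_section(m, 1, 1), class = "dendrofire_argument_error")
  expect_error(split_section(m, 999, 0.5),
               class = "dendrofire_argument_error")
})
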