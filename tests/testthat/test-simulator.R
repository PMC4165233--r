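# Analytic comparisons use a uniform passive membrane: pushing the sigmoid
# midpoints to infinity makes Rm = 30 kOhm cm2 everywhere.
uniform_passive <- function() {
  passive_profile(basal_x_half = 1e9, apical_x_half = 1e9)
}

test_that("discretize conserves membrane area", {
  fx <- fixture_suite()
  # single-point soma: sphere of radius 8 um
  g <- discretize(build_cell_spec(fx$soma_only))
  expect_equal(nrow(g$comps), 1L)
  expect_equal(g$comps$area_cm2, 4 * pi * (8e-4)^2)

  # stick: soma sphere + cylinder 2*pi*r*L
  g2 <- discretize(build_cell_spec(fx$stick), max_seg_length = 20)
  lam <- total_length(fx$stick)
  expect_equal(sum(g2$comps$area_cm2),
               4 * pi * (8e-4)^2 + 2 * pi * 1e-4 * lam * 1e-4,
               tolerance = 1e-12)
  # compartment lengths tile the cable
  expect_equal(sum(g2$comps$length_um), lam, tolerance = 1e-9)
  expect_true(all(g2$comps$length_um[-1] <= 20 + 1e-9))
})

test_that("area is conserved for arbitrary branched trees", {
  for (seed in c(31, 64)) {
    m <- random_test_tree(seed)
    g <- discretize(build_cell_spec(m), max_seg_length = 11)
    pts <- m$points
    rows <- match(pts$parent_id, pts$id)
    ok <- !is.na(rows) & pts$structure == 3L
    l <- sqrt((pts$x[ok] - pts$x[rows[ok]])^2 +
                (pts$y[ok] - pts$y[rows[ok]])^2 +
                (pts$z[ok] - pts$z[rows[ok]])^2)
    # frustum lateral area per segment, with the soma-to-stem attachment
    # segment taking the child radius (matching the section convention)
    r_child <- pts$radius[ok]
    r_par <- pts$radius[rows[ok]]
    cross <- pts$structure[rows[ok]] != pts$structure[ok]
    r_par[cross] <- r_child[cross]
    area_um2 <- sum(2 * pi * (r_par + r_child) / 2 * l)
    dend <- g$comps$region == "basal"
    expect_equal(sum(g$comps$area_cm2[dend]), area_um2 * 1e-8,
                 tolerance = 1e-9)
  }
})

test_that("discretize validates arguments", {
  fx <- fixture_suite()
  expect_error(discretize(build_cell_spec(fx$y_tree), max_seg_length = 0),
               class = "dendrofire_argument_error")
})

test_that("isopotential RC charging matches the closed form with tau 36 ms", {
  g <- discretize(build_cell_spec(fixture_suite()$soma_only,
                                  passive = uniform_passive()))
  amp <- 0.02
  tr <- simulate_cell(g, step_protocol(amp, 20, 320, 340), dt = 0.01,
                      passive_only = TRUE)
  rin_mohm <- 30000 / (4 * pi * (8e-4)^2) * 1e-6  # Rm / area
  tau <- 30 * 1.2  # Rm [kOhm cm2] * Cm [uF/cm2] = 36 ms
  sel <- tr$t_ms >= 20 & tr$t_ms <= 320
  v_pred <- -66 + amp * rin_mohm * (1 - exp(-(tr$t_ms[sel] - 20) / tau))
  dv_max <- amp * rin_mohm
  expect_lt(max(abs(tr$v_mv[sel] - v_pred)) / dv_max, 0.01)
})

test_that("sealed-end cable input resistance matches R_inf coth(L/lambda)", {
  fx <- fixture_suite()
  spec <- build_cell_spec(fx$cable, passive = uniform_passive())
  g <- discretize(spec, max_seg_length = 5)
  rin <- measure_input_resistance(g, passive_only = TRUE)
  a_cm <- 1e-4
  r_inf <- sqrt(30000 * 210 / (2 * pi^2 * a_cm^3)) * 1e-6  # MOhm
  rin_theory <- r_inf / tanh(1)  # L = lambda by construction
  expect_lt(abs(rin - rin_theory) / rin_theory, 0.01)
})

test_that("spatial refinement converges", {
  fx <- fixture_suite()
  spec <- build_cell_spec(fx$stick, passive = uniform_passive())
  r20 <- measure_input_resistance(discretize(spec, max_seg_length = 20),
                                  passive_only = TRUE)
  r5 <- measure_input_resistance(discretize(spec, max_seg_length = 5),
                                 passive_only = TRUE)
  expect_lt(abs(r20 - r5) / r5, 0.01)
})

test_that("simulation is deterministic and settles to rest", {
  fx <- fixture_suite()
  g <- discretize(build_cell_spec(graft(fx$soma_only, fx$y_tree,
                                        fx$apical_simple)))
  prot <- step_protocol(0, 10, 40, 50)
  t1 <- simulate_cell(g, prot)
  t2 <- simulate_cell(g, prot)
  expect_identical(t1$v_mv, t2$v_mv)
  # no stimulus: membrane stays near rest for the whole trace
  expect_lt(max(abs(t1$v_mv - t1$v_mv[1])), 0.5)
  expect_lt(abs(t1$v_mv[1] - (-66)), 2)
})

test_that("voltage traces round-trip through write/read", {
  g <- discretize(build_cell_spec(fixture_suite()$soma_only))
  tr <- simulate_cell(g, step_protocol(0.05, 5, 20, 25), dt = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$v_mv, tr$v_mv, tolerance = 1e-8)
  expect_equal(attr(tr2, "dt"), attr(tr, "dt"))
})

test_that("step_protocol validates times", {
  expect_error(step_protocol(0.1, t_start = 100, t_end = 50),
               class = "dendrofire_argument_error")
})
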