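# Independent oracle implementations used by the property tests.  These are
# deliberately written with different algorithms than the package code.

# Brute-force MEP: enumerate every terminal section and walk its parent
# chain upward, summing l/lambda per section (the package accumulates
# downward instead).
mep_bruteforce <- function(m, tree = "basal",
                           consts = electrotonic_constants()) {
  code <- if (tree == "basal") 3L else 4L
  sec <- sections(m)
  if (!any(sec$structure == code)) return(0)
  b_cm <- (sec$diameter / 2) * 1e-4
  lam_um <- sqrt(b_cm * consts$rm_ohm_cm2 / (2 * consts$ra_ohm_cm)) * 1e4
  Lambda <- sec$length / lam_um
  tips <- which(sec$structure == code & sec$is_tip)
  paths <- vapply(tips, function(s) {
    total <- 0
    while (!is.na(s) && sec$structure[s] == code) {
      total <- total + Lambda[s]
      s <- sec$parent_section[s]
    }
    total
  }, numeric(1))
  mean(paths)
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# rank-subset assignments (tie-free samples only), using the same
# two-sided convention as R's exact wilcox.test.
mw_enum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  subsets <- utils::combn(n + m, n)
  u_all <- apply(subsets, 2, function(s) sum(r[s]) - n * (n + 1) / 2)
  if (u_obs > n * m / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(1, p)
}

# Small random morphology for property tests (deterministic per seed).
random_test_tree <- function(seed) {
  local_seed(seed, {
    generate_tree(tree_recipe(
      n_stems = sample(1:4, 1), bif_prob = runif(1, 0.1, 0.7),
      seg_length_mean = runif(1, 25, 80), seg_length_sd = runif(1, 3, 15),
      stem_diameter = runif(1, 0.6, 1.6), taper = runif(1, 0.6, 1),
      max_depth = sample(1:3, 1), max_segments = sample(1:3, 1),
      seed = seed + 1L))
  })
}
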