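# Synthetic dendritic morphologies with controllable size and topology.
#
# Trees are grown stem by stem with strictly binary branching: a branch is a
# run of straight segments; after each segment the branch either bifurcates
# (probability `bif_prob`, while below `max_depth`), or continues, and it
# terminates once `max_segments` segments have been laid down without a
# fork.  Child branches inherit a fraction `taper` of the parent diameter,
# so the radius is constant within each unbranched section and tapers at
# branch points.  All randomness goes through R's RNG under the recipe
# seed, so a recipe is fully reproducible.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded helpers never disturb the surrounding random stream.  With a
#' `NULL` seed the expression is evaluated unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Recipe for one synthetic dendritic tree
#'
#' @param n_stems Number of stems leaving the soma.
#' @param bif_prob Bifurcation probability per laid-down segment.
#' @param seg_length_mean,seg_length_sd Segment length, mean and SD in um
#'   (lengths are truncated below at 20% of the mean).
#' @param stem_diameter Stem diameter in um.
#' @param taper Child-to-parent diameter ratio at a branch point, in (0, 1].
#' @param max_depth Maximum branch order at which bifurcation is allowed.
#' @param max_segments Segments per branch before it terminates as a tip.
#' @param tree Tree class to generate: `"basal"` or `"apical"`.
#' @param soma_radius Radius of the single-point soma sphere, um.
#' @param jitter Direction persistence jitter (SD of the per-step random
#'   deflection added to the current unit direction).
#' @param seed Integer seed; the same recipe always yields the same tree.
#' @return A list of class `tree_recipe`.
#' @export
tree_recipe <- function(n_stems = 5, bif_prob = 0.45,
                        seg_length_mean = 55, seg_length_sd = 14,
                        stem_diameter = 1.2, taper = 0.85,
                        max_depth = 3, max_segments = 3,
                        tree = "basal", soma_radius = 8,
                        jitter = 0.4, seed = 1L) {
  if (n_stems < 1) abort("n_stems must be >= 1", class = "dendrofire_argument_error")
  if (bif_prob < 0 || bif_prob > 1) {
    abort("bif_prob must be in [0, 1]", class = "dendrofire_argument_error")
  }
  if (seg_length_mean <= 0 || stem_diameter <= 0 || soma_radius <= 0) {
    abort("lengths and diameters must be positive",
          class = "dendrofire_argument_error")
  }
  if (taper <= 0 || taper > 1) {
    abort("taper must be in (0, 1]", class = "dendrofire_argument_error")
  }
  if (max_segments < 1) {
    abort("recipe would yield zero segments per branch",
          class = "dendrofire_argument_error")
  }
  structure(
    list(n_stems = as.integer(n_stems), bif_prob = bif_prob,
         seg_length_mean = seg_length_mean, seg_length_sd = seg_length_sd,
         stem_diameter = stem_diameter, taper = taper,
         max_depth = as.integer(max_depth),
         max_segments = as.integer(max_segments),
         tree = tree, soma_radius = soma_radius, jitter = jitter,
         seed = as.integer(seed)),
    class = "tree_recipe"
  )
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

random_unit <- function() unit_vec(stats::rnorm(3))

#' Generate one synthetic morphology from a recipe
#'
#' Grows a single-point soma plus `n_stems` binary dendritic subtrees of the
#' requested class.  Deterministic given the recipe seed.
#'
#' @param recipe A [tree_recipe()].
#' @return A [morphology][as_morphology] object.
#' @export
generate_tree <- function(recipe) {
  stopifnot(inherits(recipe, "tree_recipe"))
  code <- structure_name_to_code(recipe$tree)
  local_seed(recipe$seed, {
    rows <- list(tibble(
      id = 1L, structure = SWC_STRUCTURES[["soma"]],
      x = 0, y = 0, z = 0, radius = recipe$soma_radius, parent_id = -1L
    ))
    next_id <- 1L
    draw_len <- function() {
      max(0.2 * recipe$seg_length_mean,
          stats::rnorm(1, recipe$seg_length_mean, recipe$seg_length_sd))
    }
    # iterative DFS over branches to keep the point table topologically sorted
    grow <- function(parent_id, pos, dir, diameter, depth) {
      stack <- list(list(parent = parent_id, pos = pos, dir = dir,
                         diameter = diameter, depth = depth))
      while (length(stack) > 0L) {
        br <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        cur_parent <- br$parent; cur_pos <- br$pos; cur_dir <- br$dir
        for (s in seq_len(recipe$max_segments)) {
          cur_dir <- unit_vec(cur_dir + recipe$jitter * stats::rnorm(3))
          cur_pos <- cur_pos + draw_len() * cur_dir
          next_id <<- next_id + 1L
          rows[[length(rows) + 1L]] <<- tibble(
            id = next_id, structure = code,
            x = cur_pos[1], y = cur_pos[2], z = cur_pos[3],
            radius = br$diameter / 2, parent_id = cur_parent
          )
          cur_parent <- next_id
          if (br$depth < recipe$max_depth &&
              stats::runif(1) < recipe$bif_prob) {
            ortho <- unit_vec(pracma_cross(cur_dir, random_unit()))
            for (sgn in c(1, -1)) {
              stack[[length(stack) + 1L]] <- list(
                parent = cur_parent, pos = cur_pos,
                dir = unit_vec(cur_dir + sgn * 0.8 * ortho),
                diameter = br$diameter * recipe$taper,
                depth = br$depth + 1L
              )
            }
            break
          }
        }
      }
    }
    for (st in seq_len(recipe$n_stems)) {
      dir <- random_unit()
      grow(1L, dir * recipe$soma_radius, dir, recipe$stem_diameter, 1L)
    }
    pts <- dplyr::bind_rows(rows)
    # stack order is depth-first but ids were assigned in creation order;
    # creation order guarantees parent ids precede children
    as_morphology(pts[order(pts$id), ],
                  provenance = sprintf("synthetic(seed=%d)", recipe$seed))
  })
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Recipe for a two-class synthetic population
#'
#' Defines an RS-like class of longer, bushier basal trees and an IB-like
#' class of shorter, sparser ones.  The default class recipes target median
#' basal total lengths of roughly 1.7 mm vs 1.15 mm and branch numbers of
#' roughly 15 vs 10, the size contrast reported between regular-spiking and
#' bursting layer V PFC pyramidal cell basal trees.
#'
#' @param n_per_class Number of trees per class.
#' @param rs_recipe,ib_recipe [tree_recipe()] objects for the two classes
#'   (their seeds are ignored; per-tree seeds derive from `seed`).
#' @param seed Master seed.
#' @return A list of class `population_recipe`.
#' @export
population_recipe <- function(n_per_class = 20,
                              rs_recipe = tree_recipe(
                                n_stems = 5, bif_prob = 0.33,
                                seg_length_mean = 50, seg_length_sd = 12,
                                stem_diameter = 1.15, taper = 0.85,
                                max_depth = 2, max_segments = 3),
                              ib_recipe = tree_recipe(
                                n_stems = 4, bif_prob = 0.28,
                                seg_length_mean = 48, seg_length_sd = 12,
                                stem_diameter = 0.95, taper = 0.85,
                                max_depth = 2, max_segments = 3),
                              seed = 1L) {
  if (n_per_class < 1) {
    abort("n_per_class must be >= 1 (empty population)",
          class = "dendrofire_argument_error")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 rs_recipe = rs_recipe, ib_recipe = ib_recipe,
                 seed = as.integer(seed)),
            class = "population_recipe")
}

#' Generate a two-class population of synthetic morphologies
#'
#' @param recipe A [population_recipe()].
#' @return A list with elements `morphologies` (named list) and `labels`
#'   (tibble with `id`, `class` in `{"RS", "IB"}`) giving the generating
#'   class of each tree as ground truth for recovery tests.
#' @export
generate_population <- function(recipe) {
  stopifnot(inherits(recipe, "population_recipe"))
  seeds <- local_seed(recipe$seed,
                      sample.int(.Machine$integer.max - 1L,
                                 2L * recipe$n_per_class))
  classes <- rep(c("RS", "IB"), each = recipe$n_per_class)
  base <- list(RS = recipe$rs_recipe, IB = recipe$ib_recipe)
  ms <- purrr::map(seq_along(classes), function(i) {
    r <- base[[classes[i]]]
    r$seed <- seeds[i]
    generate_tree(r)
  })
  ids <- sprintf("%s_%02d", tolower(classes),
                 c(seq_len(recipe$n_per_class), seq_len(recipe$n_per_class)))
  names(ms) <- ids
  list(morphologies = ms,
       labels = tibble(id = ids, class = classes))
}

#' Deterministic basal load ladder
#'
#' Builds a sequence of regular multi-stem basal trees of increasing total
#' length (1, 2, ... stems of identical straight cables radiating from a
#' single-point soma).  Because every rung adds one identical stem, the
#' somatic load grows monotonically with total length, which makes the
#' ladder the canonical probe for the headline morphology-firing direction:
#' attached basal load up, first interspike interval up (bursting cells
#' below the RS/IB threshold, regular-spiking cells above it).
#'
#' @param n_steps Number of rungs (trees); rung k has k stems.
#' @param stem_length_um Length of each unbranched stem, um.
#' @param stem_radius_um Radius of each stem, um.
#' @param soma_radius_um Radius of the single-point soma, um.
#' @param points_per_stem Sample points per stem (at least 2).
#' @return A list of `n_steps` morphologies ordered by total length.
#' @export
basal_load_ladder <- function(n_steps = 5, stem_length_um = 250,
                              stem_radius_um = 0.7, soma_radius_um = 8,
                              points_per_stem = 10) {
  if (n_steps < 1 || points_per_stem < 2) {
    abort("n_steps must be >= 1 and points_per_stem >= 2",
          class = "dendrofire_argument_error")
  }
  purrr::map(seq_len(n_steps), function(nstem) {
    rows <- list(tibble(id = 1L, structure = 1L, x = 0, y = 0, z = 0,
                        radius = soma_radius_um, parent_id = -1L))
    nid <- 1L
    for (s in seq_len(nstem)) {
      th <- 2 * pi * s / nstem
      xs <- seq(stem_length_um / points_per_stem, stem_length_um,
                length.out = points_per_stem)
      ids <- nid + seq_len(points_per_stem)
      rows[[s + 1L]] <- tibble(
        id = ids, structure = 3L, x = xs * cos(th), y = xs * sin(th), z = 0,
        radius = stem_radius_um,
        parent_id = c(1L, ids[-points_per_stem]))
      nid <- nid + points_per_stem
    }
    as_morphology(dplyr::bind_rows(rows),
                  provenance = sprintf("ladder(stems=%d)", nstem))
  })
}

#' Small named fixture morphologies
#'
#' A deterministic suite of minimal morphologies used throughout the tests
#' and examples:
#' \describe{
#'   \item{soma_only}{A single-point soma sphere (radius 8 um).}
#'   \item{stick}{Soma plus one unbranched basal cable of radius 1 um whose
#'     length equals one electrotonic length constant under the default
#'     constants, so its MEP is exactly 1.}
#'   \item{cable}{The same unbranched cable without a soma (root is a
#'     dendritic point), for analytic finite-cable comparisons.}
#'   \item{y_tree}{Soma plus one basal stem that bifurcates once
#'     (branch number 3).}
#'   \item{basal3}{A three-stem basal mini-cell.}
#'   \item{basal_control}{A mid-sized four-stem basal tree; grafted with
#'     `apical_simple` onto the standard soma it forms the reference
#'     ("control") cell whose input resistance anchors the normalized
#'     current-step protocol.}
#'   \item{apical_complex, apical_simple}{A long, branched vs a short,
#'     sparse apical tree on the same soma.}
#' }
#'
#' @param consts Electrotonic constants used to size the unit-lambda stick.
#' @return A named list of morphologies.
#' @export
fixture_suite <- function(consts = electrotonic_constants()) {
  lam <- section_lambda_um(1, consts)  # radius 1 um

  soma_pt <- tibble(id = 1L, structure = 1L, x = 0, y = 0, z = 0,
                    radius = 8, parent_id = -1L)
  soma_only <- as_morphology(soma_pt, provenance = "fixture:soma_only")

  n_seg <- 10L
  xs <- seq(lam / n_seg, lam, length.out = n_seg)
  stick <- as_morphology(
    dplyr::bind_rows(
      soma_pt,
      tibble(id = 1L + seq_len(n_seg), structure = 3L, x = xs, y = 0, z = 0,
             radius = 1, parent_id = c(1L, 1L + seq_len(n_seg - 1L)))
    ), provenance = "fixture:stick")

  cable <- as_morphology(
    tibble(id = seq_len(n_seg + 1L), structure = 3L,
           x = c(0, xs), y = 0, z = 0, radius = 1,
           parent_id = c(-1L, seq_len(n_seg))),
    provenance = "fixture:cable")

  y_tree <- as_morphology(
    dplyr::bind_rows(
      soma_pt,
      tibble(id = 2:3, structure = 3L, x = c(50, 100), y = 0, z = 0,
             radius = 0.6, parent_id = c(1L, 2L)),
      tibble(id = 4:5, structure = 3L, x = 150, y = c(40, -40), z = 0,
             radius = 0.5, parent_id = c(3L, 3L)),
      tibble(id = 6:7, structure = 3L, x = 200, y = c(70, -70), z = 0,
             radius = 0.5, parent_id = c(4L, 5L))
    ), provenance = "fixture:y_tree")

  basal3 <- generate_tree(tree_recipe(
    n_stems = 3, bif_prob = 0.5, seg_length_mean = 40, seg_length_sd = 8,
    stem_diameter = 1.1, max_depth = 2, max_segments = 2, seed = 101L))
  basal3$provenance <- "fixture:basal3"

  basal_control <- generate_tree(tree_recipe(
    n_stems = 4, bif_prob = 0.28, seg_length_mean = 52, seg_length_sd = 12,
    stem_diameter = 1.0, taper = 0.85, max_depth = 2, max_segments = 3,
    seed = 204L))
  basal_control$provenance <- "fixture:basal_control"

  apical_complex <- generate_tree(tree_recipe(
    n_stems = 1, bif_prob = 0.5, seg_length_mean = 85, seg_length_sd = 18,
    stem_diameter = 0.95, taper = 0.8, max_depth = 3, max_segments = 3,
    tree = "apical", seed = 202L))
  apical_complex$provenance <- "fixture:apical_complex"

  apical_simple <- generate_tree(tree_recipe(
    n_stems = 1, bif_prob = 0.15, seg_length_mean = 70, seg_length_sd = 15,
    stem_diameter = 1.1, taper = 0.8, max_depth = 2, max_segments = 3,
    tree = "apical", seed = 203L))
  apical_simple$provenance <- "fixture:apical_simple"

  list(soma_only = soma_only, stick = stick, cable = cable, y_tree = y_tree,
       basal3 = basal3, basal_control = basal_control,
       apical_complex = apical_complex, apical_simple = apical_simple)
}
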