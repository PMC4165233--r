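# Per-tree morphometrics of basal or apical dendritic trees.
#
# Features are computed per cylindrical section (an unbranched stretch with
# a length-weighted mean diameter):
#   total length  L      = sum of section lengths                     [um]
#   volume        V      = sum_i pi * L_i * (D_i / 2)^2               [um^3]
#   median diameter      = unweighted median of section diameters     [um]
#   branch number        = number of unbranched topological segments
#                          (stem->fork, fork->fork, fork->tip)
#   MEP                  = mean electrotonic path length (dimensionless):
#                          each section's dimensionless length is
#                          Lambda_i = l_i / lambda_i with
#                          lambda_i = sqrt(b_i * r_m / (2 * r_a)), b_i the
#                          section radius; the path sum P_j runs from the
#                          tip of terminal section j to the subtree root,
#                          and MEP is the mean of P_j over the N terminals.
# All features are invariant to translation and rotation of coordinates.

#' Electrotonic constants for the mean electrotonic path length
#'
#' Constant specific membrane resistance and intracellular resistivity used
#' in the electrotonic length constant \eqn{\lambda_i = \sqrt{b_i r_m /
#' (2 r_a)}}.  The defaults are the somatic passive values of the cell
#' model: \eqn{r_m} = 30 kOhm cm^2 and \eqn{r_a} = 210 Ohm cm.  Note these
#' are deliberately position-independent even though the simulated membrane
#' resistance varies with distance from the soma: MEP is a purely
#' morphological/passive summary.
#'
#' @param rm_ohm_cm2 Specific membrane resistance, Ohm cm^2.
#' @param ra_ohm_cm Intracellular resistivity, Ohm cm.
#' @return A list of class `electrotonic_constants`.
#' @export
electrotonic_constants <- function(rm_ohm_cm2 = 30000, ra_ohm_cm = 210) {
  if (rm_ohm_cm2 <= 0 || ra_ohm_cm <= 0) {
    abort("electrotonic constants must be positive",
          class = "dendrofire_argument_error")
  }
  structure(list(rm_ohm_cm2 = rm_ohm_cm2, ra_ohm_cm = ra_ohm_cm),
            class = "electrotonic_constants")
}

tree_sections <- function(m, tree, topological = FALSE) {
  code <- structure_name_to_code(tree)
  sec <- sections(m, topological = topological)
  sec[sec$structure == code, ]
}

#' Total dendritic length of a tree
#'
#' Sum of section lengths (equivalently, of all inter-point 3D distances)
#' over the basal or apical subtree(s), in micrometres.
#'
#' @param m A morphology.
#' @param tree `"basal"` or `"apical"` (or an SWC structure code).
#' @return Length in micrometres.
#' @export
total_length <- function(m, tree = "basal") {
  sec <- tree_sections(m, tree)
  if (nrow(sec) == 0L) {
    warn(paste0("empty ", tree, " tree: total length 0"))
    return(0)
  }
  sum(sec$length)
}

#' Tree volume
#'
#' Treats each section as a cylinder: \eqn{V = \sum_i \pi L_i (D_i/2)^2}
#' with \eqn{L_i} the section length and \eqn{D_i} its length-weighted mean
#' diameter, in cubic micrometres.
#'
#' @inheritParams total_length
#' @return Volume in um^3.
#' @export
tree_volume <- function(m, tree = "basal") {
  sec <- tree_sections(m, tree)
  if (nrow(sec) == 0L) return(0)
  sum(pi * sec$length * (sec$diameter / 2)^2)
}

#' Median section diameter of a tree
#'
#' One diameter per cylindrical section (unweighted median over sections);
#' the midpoint of the two central values is used for an even section
#' count.
#'
#' @inheritParams total_length
#' @return Diameter in micrometres.
#' @export
median_diameter <- function(m, tree = "basal") {
  sec <- tree_sections(m, tree)
  if (nrow(sec) == 0L) {
    abort(paste0("median diameter undefined for an empty ", tree, " tree"),
          class = "dendrofire_value_error")
  }
  median(sec$diameter)
}

#' Branch number of a tree
#'
#' Number of unbranched topological segments (stem to fork, fork to fork,
#' fork to tip).  For a strictly binary subtree with T tips this equals
#' 2T - 1.  Section boundaries introduced by [split_section()] are ignored:
#' only true forks and terminals delimit branches.
#'
#' @inheritParams total_length
#' @return Integer count.
#' @export
branch_number <- function(m, tree = "basal") {
  nrow(tree_sections(m, tree, topological = TRUE))
}

#' Mean electrotonic path length (MEP)
#'
#' Each section's length is normalised by its electrotonic length constant
#' \eqn{\lambda_i = \sqrt{b_i r_m / (2 r_a)}} (radius \eqn{b_i} and length
#' converted to cm), giving a dimensionless \eqn{\Lambda_i = l_i/\lambda_i}.
#' For each terminal section j, \eqn{P_j} is the sum of \eqn{\Lambda_i}
#' along the path from the tip to the subtree root (not through the soma),
#' and MEP is the mean of \eqn{P_j} over the N terminals.  Computed by a
#' single downward accumulation over the section tree.
#'
#' @inheritParams total_length
#' @param consts An [electrotonic_constants()] object.
#' @return Dimensionless MEP (0 for an empty tree).
#' @export
mep <- function(m, tree = "basal", consts = electrotonic_constants()) {
  stopifnot(inherits(consts, "electrotonic_constants"))
  code <- structure_name_to_code(tree)
  sec <- sections(m)
  if (!any(sec$structure == code)) return(0)
  lam <- section_lambda_um(sec$diameter / 2, consts)
  Lambda <- sec$length / lam
  # downward accumulation: sections appear in an order where each parent
  # section precedes its children
  path <- numeric(nrow(sec))
  for (s in seq_len(nrow(sec))) {
    if (sec$structure[s] != code) next
    p <- sec$parent_section[s]
    inherited <- if (!is.na(p) && sec$structure[p] == code) path[p] else 0
    path[s] <- inherited + Lambda[s]
  }
  tips <- sec$structure == code & sec$is_tip
  if (!any(tips)) return(0)
  mean(path[tips])
}

# electrotonic length constant in micrometres for radius b (um)
section_lambda_um <- function(b_um, consts) {
  if (any(b_um <= 0)) {
    abort("zero or negative section radius in MEP computation",
          class = "dendrofire_value_error")
  }
  b_cm <- b_um * 1e-4
  lam_cm <- sqrt(b_cm * consts$rm_ohm_cm2 / (2 * consts$ra_ohm_cm))
  lam_cm * 1e4
}

#' Morphometric feature vector of one or more trees
#'
#' Computes the five per-tree features (median diameter, total length,
#' volume, branch number, MEP) for each requested tree class of each
#' morphology, returning one row per (morphology, tree class).
#'
#' @param m A morphology or a (possibly named) list of morphologies.
#' @param tree Character vector of tree classes (`"basal"`, `"apical"`).
#' @param consts An [electrotonic_constants()] object.
#' @return A tibble with columns `file`, `tree`, `median_diameter_um`,
#'   `total_length_um`, `volume_um3`, `branch_number`, `mep`.
#' @export
morpho_features <- function(m, tree = "basal",
                            consts = electrotonic_constants()) {
  ms <- if (inherits(m, "morphology")) list(m) else m
  nm <- names(ms)
  if (is.null(nm)) {
    nm <- vapply(ms, function(x) paste(x$provenance, collapse = "; "),
                 character(1))
  }
  purrr::map_dfr(seq_along(ms), function(i) {
    purrr::map_dfr(tree, function(tr) {
      tibble(
        file = nm[i], tree = tr,
        median_diameter_um = median_diameter(ms[[i]], tr),
        total_length_um = total_length(ms[[i]], tr),
        volume_um3 = tree_volume(ms[[i]], tr),
        branch_number = branch_number(ms[[i]], tr),
        mep = mep(ms[[i]], tr, consts)
      )
    })
  })
}
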