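# SWC structure codes used throughout: 1 = soma, 2 = axon, 3 = basal
# dendrite, 4 = apical dendrite.  Coordinates and radii are micrometres;
# column 6 of an SWC file is a radius, not a diameter.

SWC_STRUCTURES <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L)

#' Construct a morphology from an SWC point table
#'
#' A morphology is a rooted tree of points in the standard SWC sense:
#' each point has an id, a structure code (1 soma, 2 axon, 3 basal dendrite,
#' 4 apical dendrite), 3D coordinates and a radius in micrometres, and a
#' parent id (-1 for the single root).  On construction the point table is
#' validated (positive radii, topological id order, single root, known
#' structure codes, parents present) and partitioned into unbranched
#' sections.
#'
#' @param points A data frame with columns `id`, `structure`, `x`, `y`, `z`,
#'   `radius`, `parent_id`.
#' @param provenance Character vector recording where the points came from.
#' @param breaks Integer vector of point ids that force a section boundary
#'   in addition to the topological ones (used by [split_section()]).
#' @return An object of class `morphology`.
#' @export
as_morphology <- function(points, provenance = "in-memory", breaks = integer()) {
  pts <- as_tibble(points)
  required <- c("id", "structure", "x", "y", "z", "radius", "parent_id")
  if (!all(required %in% names(pts))) {
    abort(paste0("points must have columns: ", paste(required, collapse = ", ")),
          class = "dendrofire_validation_error")
  }
  pts <- pts[required]
  pts$id <- as.integer(pts$id)
  pts$structure <- as.integer(pts$structure)
  pts$parent_id <- as.integer(pts$parent_id)
  validate_swc_points(pts)
  structure(
    list(points = pts, breaks = as.integer(breaks), provenance = provenance),
    class = "morphology"
  )
}

validate_swc_points <- function(pts) {
  if (nrow(pts) == 0L) {
    abort("SWC point table is empty", class = "dendrofire_validation_error")
  }
  if (anyNA(pts)) {
    abort("SWC point table contains missing values",
          class = "dendrofire_validation_error")
  }
  bad_struct <- pts$id[!pts$structure %in% SWC_STRUCTURES]
  if (length(bad_struct) > 0L) {
    abort(paste0("unknown structure code at point id(s): ",
                 paste(head(bad_struct, 5L), collapse = ", ")),
          class = "dendrofire_validation_error")
  }
  if (any(pts$radius <= 0)) {
    abort(paste0("non-positive radius at point id(s): ",
                 paste(head(pts$id[pts$radius <= 0], 5L), collapse = ", ")),
          class = "dendrofire_validation_error")
  }
  if (anyDuplicated(pts$id)) {
    abort("duplicate point ids", class = "dendrofire_validation_error")
  }
  roots <- pts$id[pts$parent_id == -1L]
  if (length(roots) != 1L) {
    abort(paste0("expected exactly one root (parent_id -1), found ",
                 length(roots)),
          class = "dendrofire_validation_error")
  }
  # topological order rules out cycles: every parent precedes its child
  not_sorted <- pts$parent_id >= pts$id
  if (any(not_sorted)) {
    abort(paste0("point id(s) not topologically sorted (parent_id >= id): ",
                 paste(head(pts$id[not_sorted], 5L), collapse = ", ")),
          class = "dendrofire_structural_error")
  }
  missing_parent <- pts$parent_id != -1L & !pts$parent_id %in% pts$id
  if (any(missing_parent)) {
    abort(paste0("parent id not present for point(s): ",
                 paste(head(pts$id[missing_parent], 5L), collapse = ", ")),
          class = "dendrofire_structural_error")
  }
  invisible(pts)
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column whitespace-separated SWC format
#' (`id structure x y z radius parent_id`; lines starting with `#` are
#' comments).  Units are taken as micrometres.
#'
#' @param path Path to an SWC file.
#' @return A [morphology][as_morphology] object.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("SWC file not found: ", path), class = "dendrofire_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    abort(paste0("no data lines in SWC file: ", path),
          class = "dendrofire_validation_error")
  }
  fields <- strsplit(lines, "[[:space:]]+")
  ncols <- lengths(fields)
  if (any(ncols != 7L)) {
    abort(paste0("SWC line(s) without 7 columns: line ",
                 which(ncols != 7L)[1L]),
          class = "dendrofire_validation_error")
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(mat)) {
    abort("non-numeric field in SWC file", class = "dendrofire_validation_error")
  }
  pts <- tibble(
    id = as.integer(mat[, 1L]), structure = as.integer(mat[, 2L]),
    x = mat[, 3L], y = mat[, 4L], z = mat[, 5L],
    radius = mat[, 6L], parent_id = as.integer(mat[, 7L])
  )
  as_morphology(pts, provenance = basename(path))
}

#' Write a morphology to an SWC file
#'
#' Writes the standard 7-column format with a `#` provenance header.
#' Coordinates and radii are written with enough digits for a lossless
#' round-trip at micrometre scale.
#'
#' @param m A morphology.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  header <- c(
    "# SWC written by dendrofire",
    paste0("# provenance: ", paste(m$provenance, collapse = "; ")),
    "# columns: id structure x y z radius parent_id (um)"
  )
  body <- sprintf(
    "%d %d %.9g %.9g %.9g %.9g %d",
    m$points$id, m$points$structure, m$points$x, m$points$y, m$points$z,
    m$points$radius, m$points$parent_id
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.morphology <- function(x, ...) {
  sec <- sections(x)
  cat("<morphology> ", nrow(x$points), " points, ", nrow(sec), " sections (",
      paste(sprintf("%s: %d", names(SWC_STRUCTURES),
                    vapply(SWC_STRUCTURES, function(s) sum(sec$structure == s),
                           integer(1))),
            collapse = ", "),
      ")\n  provenance: ", paste(x$provenance, collapse = "; "), "\n", sep = "")
  invisible(x)
}

# children_map: list indexed by position-in-table, child ids in id order
children_map <- function(pts) {
  idx <- match(pts$parent_id, pts$id)
  ch <- vector("list", nrow(pts))
  ord <- order(pts$id)
  for (i in ord) {
    p <- idx[i]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], pts$id[i])
  }
  ch
}

#' Partition a morphology into unbranched sections
#'
#' A section is an ordered run of points spanning one unbranched stretch:
#' it ends at a branch point, a terminal, or a structure change.  The first
#' listed point of each section is its attachment point (the parent point
#' from which the stretch departs), so a section of k points has k - 1
#' inter-point segments.  The partition covers every non-root point exactly
#' once.
#'
#' The section diameter is the length-weighted mean of the point diameters
#' along the stretch.  The attachment segment always contributes at the
#' child point's diameter: the attachment point belongs to the parent
#' section (a fork of the parent branch, or the soma), so its radius must
#' not contaminate the section's own diameter.  With this convention the
#' diameter (and hence volume and electrotonic length) of trees whose
#' radius is constant within each branch is exactly invariant under
#' [split_section()].
#'
#' @param m A morphology.
#' @param topological If `TRUE`, ignore extra break points introduced by
#'   [split_section()] and return the purely topological partition (used
#'   for branch counting).
#' @return A tibble with one row per section: `section_id`, `structure`,
#'   `parent_section`, `point_ids` (list column, attachment point first),
#'   `length`, `diameter`, `n_segments`, `is_tip`.
#' @export
sections <- function(m, topological = FALSE) {
  pts <- m$points
  n <- nrow(pts)
  ch <- children_map(pts)
  id2row <- seq_len(n)
  names(id2row) <- as.character(pts$id)
  row_of <- function(id) id2row[[as.character(id)]]
  root_row <- which(pts$parent_id == -1L)
  breaks <- if (topological) integer() else m$breaks

  n_children <- lengths(ch)
  is_break <- n_children != 1L | pts$id %in% breaks
  is_break[root_row] <- TRUE

  sec_struct <- integer(); sec_pts <- list(); sec_start <- integer()
  point_section <- rep(NA_integer_, n)  # section membership of non-start pts

  for (i in seq_len(n)) {
    if (i == root_row) next
    p_row <- row_of(pts$parent_id[i])
    starts <- is_break[p_row] || pts$structure[p_row] != pts$structure[i]
    if (!starts) next
    run <- c(pts$id[p_row], pts$id[i])
    cur <- i
    point_section[cur] <- length(sec_pts) + 1L
    while (!is_break[cur] &&
           pts$structure[row_of(ch[[cur]][1L])] == pts$structure[cur]) {
      nxt <- row_of(ch[[cur]][1L])
      run <- c(run, pts$id[nxt])
      point_section[nxt] <- length(sec_pts) + 1L
      cur <- nxt
    }
    sec_pts[[length(sec_pts) + 1L]] <- run
    sec_struct <- c(sec_struct, pts$structure[i])
    sec_start <- c(sec_start, p_row)
  }

  ns <- length(sec_pts)
  len <- numeric(ns); diam <- numeric(ns); nseg <- integer(ns)
  tip <- logical(ns); parent_sec <- integer(ns)
  for (s in seq_len(ns)) {
    rows <- vapply(sec_pts[[s]], row_of, integer(1))
    dx <- diff(pts$x[rows]); dy <- diff(pts$y[rows]); dz <- diff(pts$z[rows])
    l_seg <- sqrt(dx^2 + dy^2 + dz^2)
    r_a <- pts$radius[rows[-length(rows)]]
    r_b <- pts$radius[rows[-1L]]
    s_a <- pts$structure[rows[-length(rows)]]
    s_b <- pts$structure[rows[-1L]]
    # the attachment point belongs to the parent section (or the soma), so
    # the attachment segment always takes the child-side radius; within the
    # run, segments use the mean of their endpoint radii
    r_seg <- (r_a + r_b) / 2
    r_seg[1L] <- r_b[1L]
    r_seg[s_a != s_b] <- r_b[s_a != s_b]
    len[s] <- sum(l_seg)
    diam[s] <- if (len[s] > 0) 2 * sum(l_seg * r_seg) / len[s] else
      2 * pts$radius[rows[length(rows)]]
    nseg[s] <- length(l_seg)
    last <- rows[length(rows)]
    tip[s] <- length(ch[[last]]) == 0L
    parent_sec[s] <- if (sec_start[s] == root_row) NA_integer_ else
      point_section[sec_start[s]]
  }

  tibble(
    section_id = seq_len(ns), structure = sec_struct,
    parent_section = parent_sec, point_ids = sec_pts,
    length = len, diameter = diam, n_segments = nseg, is_tip = tip
  )
}

# rows of pts belonging to structure `code`
structure_name_to_code <- function(tree) {
  if (is.character(tree)) {
    code <- SWC_STRUCTURES[match(tree, names(SWC_STRUCTURES))]
    if (anyNA(code)) {
      abort(paste0("unknown tree class: ", tree),
            class = "dendrofire_argument_error")
    }
    unname(code)
  } else {
    as.integer(tree)
  }
}

#' Graft donor dendritic trees onto a fixed soma
#'
#' Builds a chimeric morphology that keeps the soma (and axon, if any) of
#' `soma_donor`, takes all basal subtrees from `basal_donor`, and all apical
#' subtrees from `apical_donor`.  Each donor subtree keeps its offset vector
#' relative to its original attachment point and is re-parented to the soma
#' point of `soma_donor` whose direction from the soma centroid best matches
#' the subtree's original offset direction; subtree geometry is only
#' translated, never scaled or rotated, so every donor subtree's
#' morphometrics are conserved exactly.
#'
#' @param soma_donor,basal_donor,apical_donor Morphologies.
#' @return A new morphology with ids renumbered consecutively.
#' @export
graft <- function(soma_donor, basal_donor, apical_donor) {
  stopifnot(inherits(soma_donor, "morphology"),
            inherits(basal_donor, "morphology"),
            inherits(apical_donor, "morphology"))
  if (!any(basal_donor$points$structure == SWC_STRUCTURES[["basal"]])) {
    abort("basal_donor has no basal points", class = "dendrofire_graft_error")
  }
  if (!any(apical_donor$points$structure == SWC_STRUCTURES[["apical"]])) {
    abort("apical_donor has no apical points", class = "dendrofire_graft_error")
  }

  keep <- soma_donor$points$structure %in%
    SWC_STRUCTURES[c("soma", "axon")]
  base <- soma_donor$points[keep, ]
  if (!any(base$structure == SWC_STRUCTURES[["soma"]])) {
    abort("soma_donor has no soma points", class = "dendrofire_graft_error")
  }
  if (base$parent_id[1L] != -1L) {
    abort("soma_donor root must be a soma/axon point",
          class = "dendrofire_graft_error")
  }
  # renumber base points consecutively
  remap <- setNames(seq_len(nrow(base)), as.character(base$id))
  base$id <- unname(remap[as.character(base$id)])
  base$parent_id <- ifelse(base$parent_id == -1L, -1L,
                           unname(remap[as.character(base$parent_id)]))

  soma_rows <- base[base$structure == SWC_STRUCTURES[["soma"]], ]
  centroid <- c(mean(soma_rows$x), mean(soma_rows$y), mean(soma_rows$z))

  out <- base
  next_id <- nrow(base)
  for (donor_info in list(list(m = basal_donor, code = SWC_STRUCTURES[["basal"]]),
                          list(m = apical_donor, code = SWC_STRUCTURES[["apical"]]))) {
    d <- donor_info$m$points
    code <- donor_info$code
    d_centroid_rows <- d[d$structure == SWC_STRUCTURES[["soma"]], ]
    d_centroid <- if (nrow(d_centroid_rows) > 0) {
      c(mean(d_centroid_rows$x), mean(d_centroid_rows$y), mean(d_centroid_rows$z))
    } else c(0, 0, 0)
    # subtree stems: points of `code` whose parent is not of `code`
    idx <- match(d$parent_id, d$id)
    is_stem <- d$structure == code &
      (d$parent_id == -1L | d$structure[idx] != code)
    for (stem_row in which(is_stem)) {
      sub_rows <- collect_subtree(d, stem_row)
      sub <- d[sub_rows, ]
      old_parent_row <- idx[stem_row]
      old_parent_pos <- if (is.na(old_parent_row)) d_centroid else
        c(d$x[old_parent_row], d$y[old_parent_row], d$z[old_parent_row])
      dir <- c(d$x[stem_row], d$y[stem_row], d$z[stem_row]) - d_centroid
      if (sum(dir^2) == 0) dir <- c(1, 0, 0)
      # soma point of the recipient whose direction best matches `dir`
      sx <- soma_rows$x - centroid[1]; sy <- soma_rows$y - centroid[2]
      sz <- soma_rows$z - centroid[3]
      norms <- sqrt(sx^2 + sy^2 + sz^2)
      cosim <- (sx * dir[1] + sy * dir[2] + sz * dir[3]) /
        (pmax(norms, 1e-12) * sqrt(sum(dir^2)))
      cosim[norms == 0] <- 0
      target <- soma_rows[which.max(cosim), ]
      shift <- c(target$x, target$y, target$z) - old_parent_pos
      sub$x <- sub$x + shift[1]; sub$y <- sub$y + shift[2]
      sub$z <- sub$z + shift[3]
      sub$structure <- code
      remap_sub <- setNames(next_id + seq_len(nrow(sub)), as.character(sub$id))
      new_parent <- unname(remap_sub[as.character(sub$parent_id)])
      sub$parent_id <- ifelse(is.na(new_parent), target$id, as.integer(new_parent))
      sub$id <- unname(remap_sub[as.character(sub$id)])
      next_id <- next_id + nrow(sub)
      out <- rbind(out, sub)
    }
  }
  as_morphology(out, provenance = c(
    paste0("soma:", paste(soma_donor$provenance, collapse = "+")),
    paste0("basal:", paste(basal_donor$provenance, collapse = "+")),
    paste0("apical:", paste(apical_donor$provenance, collapse = "+"))
  ))
}

# all point rows in the subtree rooted at `root_row` (inclusive), in id order
collect_subtree <- function(pts, root_row) {
  idx <- match(pts$parent_id, pts$id)
  in_sub <- logical(nrow(pts))
  in_sub[root_row] <- TRUE
  ord <- order(pts$id)
  for (i in ord) {
    p <- idx[i]
    if (!is.na(p) && in_sub[p]) in_sub[i] <- TRUE
  }
  which(in_sub)
}

#' Split a section at a fractional arc-length position
#'
#' Inserts a new point at the given fraction of the section's length (radius
#' linearly interpolated within the containing segment) and marks it as a
#' section boundary, so the section becomes two collinear sections.  The
#' operation preserves geometry: total length, volume and mean electrotonic
#' path length of the tree are unchanged (exactly so for sections of
#' constant radius).
#'
#' @param m A morphology.
#' @param section_id Section id as returned by [sections()].
#' @param fraction Position along the section, strictly between 0 and 1.
#' @return A new morphology with ids renumbered consecutively.
#' @export
split_section <- function(m, section_id, fraction) {
  stopifnot(inherits(m, "morphology"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    abort("fraction must be strictly between 0 and 1",
          class = "dendrofire_argument_error")
  }
  sec <- sections(m)
  if (!section_id %in% sec$section_id) {
    abort(paste0("no such section: ", section_id),
          class = "dendrofire_argument_error")
  }
  ids <- sec$point_ids[[which(sec$section_id == section_id)]]
  pts <- m$points
  rows <- match(ids, pts$id)
  dx <- diff(pts$x[rows]); dy <- diff(pts$y[rows]); dz <- diff(pts$z[rows])
  l_seg <- sqrt(dx^2 + dy^2 + dz^2)
  total <- sum(l_seg)
  if (total <= 0) {
    abort("cannot split a zero-length section",
          class = "dendrofire_argument_error")
  }
  target <- fraction * total
  cum <- cumsum(l_seg)
  seg <- which(cum >= target - 1e-12)[1L]
  before <- if (seg == 1L) 0 else cum[seg - 1L]
  f_seg <- (target - before) / l_seg[seg]
  a <- rows[seg]; b <- rows[seg + 1L]

  new_pt <- tibble(
    id = NA_integer_, structure = pts$structure[b],
    x = pts$x[a] + f_seg * (pts$x[b] - pts$x[a]),
    y = pts$y[a] + f_seg * (pts$y[b] - pts$y[a]),
    z = pts$z[a] + f_seg * (pts$z[b] - pts$z[a]),
    radius = pts$radius[a] + f_seg * (pts$radius[b] - pts$radius[a]),
    parent_id = pts$id[a]
  )
  # a split inside the attachment segment takes the child-side radius: the
  # attachment point's radius describes the parent section, and the section
  # diameter convention already reads this segment at the child radius
  if (seg == 1L) {
    new_pt$radius <- pts$radius[b]
  }

  # insert immediately before row b; original order is topological, and the
  # new point's parent (a) precedes it while b re-parents to the new point
  b_pos <- b
  upper <- pts[seq_len(b_pos - 1L), ]
  lower <- pts[seq(b_pos, nrow(pts)), ]
  new_tab <- rbind(upper, new_pt, lower)
  # temporary unique ids: position order is topological, renumber 1..n
  old_ids <- new_tab$id
  new_tab$id <- seq_len(nrow(new_tab))
  new_pos <- b_pos  # position of inserted point
  remap <- setNames(new_tab$id[-new_pos], as.character(old_ids[-new_pos]))
  parents <- new_tab$parent_id
  mapped <- ifelse(parents == -1L, -1L,
                   unname(remap[as.character(parents)]))
  mapped[new_pos] <- remap[[as.character(pts$id[a])]]
  # b's parent becomes the inserted point
  b_new_pos <- new_pos + 1L
  mapped[b_new_pos] <- new_tab$id[new_pos]
  new_tab$parent_id <- as.integer(mapped)

  old_breaks <- unname(remap[as.character(m$breaks)])
  as_morphology(new_tab, provenance = m$provenance,
                breaks = c(as.integer(old_breaks), new_tab$id[new_pos]))
}
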