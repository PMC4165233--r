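# Spatial discretization and the current-clamp simulation front end.
#
# The soma is reduced to one isopotential compartment whose membrane area
# equals the summed lateral area of the soma sections (a 1-point soma
# counts as a sphere, 4*pi*r^2).  Dendritic and axonal sections are cut
# into compartments of at most `max_seg_length` um; compartment areas are
# exact integrals of the (piecewise-linear) radius profile, and axial
# resistances use the frustum form Ra * l / (pi * r_a * r_b) with half of
# each compartment's resistance on either side of its centre.

soma_area_cm2 <- function(m) {
  pts <- m$points
  root <- which(pts$parent_id == -1L)
  if (pts$structure[root] != SWC_STRUCTURES[["soma"]]) return(0)
  sec <- sections(m)
  soma_sec <- sec[sec$structure == SWC_STRUCTURES[["soma"]], ]
  if (nrow(soma_sec) == 0L || sum(soma_sec$length) == 0) {
    return(4 * pi * (pts$radius[root] * 1e-4)^2)  # sphere
  }
  area_um2 <- sum(vapply(seq_len(nrow(soma_sec)), function(s) {
    ids <- soma_sec$point_ids[[s]]
    rows <- match(ids, pts$id)
    l <- sqrt(diff(pts$x[rows])^2 + diff(pts$y[rows])^2 + diff(pts$z[rows])^2)
    rbar <- (pts$radius[rows[-1L]] + pts$radius[rows[-length(rows)]]) / 2
    sum(2 * pi * rbar * l)
  }, numeric(1)))
  area_um2 * 1e-8
}

#' Discretize a cell specification into a compartment graph
#'
#' @param spec A [build_cell_spec()] object (or a bare morphology, which is
#'   wrapped with defaults).
#' @param max_seg_length Maximum compartment length in um.
#' @return A list of class `compartment_graph` with a `comps` tibble
#'   (`comp`, `parent` (0 for none), `region`, `x_um` midpoint path
#'   distance from the soma, `length_um`, `area_cm2`, `g_ax_us`) and the
#'   originating `spec`.
#' @export
discretize <- function(spec, max_seg_length = 20) {
  if (inherits(spec, "morphology")) spec <- build_cell_spec(spec)
  stopifnot(inherits(spec, "cell_spec"))
  if (max_seg_length <= 0) {
    abort("max_seg_length must be positive",
          class = "dendrofire_argument_error")
  }
  m <- spec$morphology
  pts <- m$points
  ra <- spec$passive$ra_ohm_cm
  sec <- sections(m)
  root <- which(pts$parent_id == -1L)
  has_soma <- pts$structure[root] == SWC_STRUCTURES[["soma"]]

  comp_parent <- integer(); comp_region <- character()
  comp_x <- numeric(); comp_len <- numeric(); comp_area <- numeric()
  comp_rhalf_in <- numeric(); comp_rhalf_out <- numeric()
  # axial resistance accumulates per compartment; attach uses halves
  g_ax <- numeric()

  n_comp <- 0L
  soma_comp <- 0L
  soma_rhalf <- 0
  if (has_soma) {
    a <- soma_area_cm2(m)
    if (a <= 0) {
      abort("degenerate zero-area soma", class = "dendrofire_discretization_error")
    }
    n_comp <- 1L
    soma_comp <- 1L
    comp_parent <- 0L; comp_region <- "soma"; comp_x <- 0
    comp_len <- 0; comp_area <- a
    # soma as an equivalent cylinder with L = D: half axial resistance
    L_cm <- sqrt(a / pi)
    soma_rhalf <- ra * (L_cm / 2) / (pi * (L_cm / 2)^2)  # Ohm
    g_ax <- 0
  }

  soma_code <- SWC_STRUCTURES[["soma"]]
  dend_sec <- which(sec$structure != soma_code)
  if (!has_soma && sum(is.na(sec$parent_section[dend_sec])) > 1L) {
    abort("morphology without soma must be a single connected cable",
          class = "dendrofire_discretization_error")
  }
  sec_last_comp <- rep(NA_integer_, nrow(sec))
  sec_end_x <- rep(0, nrow(sec))
  sec_last_rhalf <- rep(soma_rhalf, nrow(sec))

  for (s in dend_sec) {
    ids <- sec$point_ids[[s]]
    rows <- match(ids, pts$id)
    l_seg <- sqrt(diff(pts$x[rows])^2 + diff(pts$y[rows])^2 +
                    diff(pts$z[rows])^2)
    r_a <- pts$radius[rows[-length(rows)]]
    r_b <- pts$radius[rows[-1L]]
    cross <- pts$structure[rows[-length(rows)]] != pts$structure[rows[-1L]]
    r_a[cross] <- r_b[cross]
    keep <- l_seg > 0
    l_seg <- l_seg[keep]; r_a <- r_a[keep]; r_b <- r_b[keep]
    total <- sum(l_seg)
    if (total <= 0) {
      abort("degenerate zero-length section",
            class = "dendrofire_discretization_error")
    }
    psec <- sec$parent_section[s]
    if (is.na(psec)) {
      parent_comp <- soma_comp            # 0 when no soma: becomes root
      x0 <- 0
      parent_rhalf <- soma_rhalf
    } else {
      parent_comp <- sec_last_comp[psec]
      x0 <- sec_end_x[psec]
      parent_rhalf <- sec_last_rhalf[psec]
    }
    n_sub <- max(1L, as.integer(ceiling(total / max_seg_length - 1e-9)))
    bounds <- seq(0, total, length.out = n_sub + 1L)
    cum <- cumsum(l_seg)
    start <- c(0, cum[-length(cum)])
    for (k in seq_len(n_sub)) {
      lo <- bounds[k]; hi <- bounds[k + 1L]
      # overlap of [lo, hi] with each source segment
      o_lo <- pmax(lo, start); o_hi <- pmin(hi, cum)
      ov <- which(o_hi > o_lo + 1e-12)
      area_um2 <- 0; r_axial <- 0
      for (j in ov) {
        f0 <- (o_lo[j] - start[j]) / l_seg[j]
        f1 <- (o_hi[j] - start[j]) / l_seg[j]
        rr0 <- r_a[j] + f0 * (r_b[j] - r_a[j])
        rr1 <- r_a[j] + f1 * (r_b[j] - r_a[j])
        dl <- o_hi[j] - o_lo[j]
        area_um2 <- area_um2 + 2 * pi * (rr0 + rr1) / 2 * dl
        r_axial <- r_axial + ra * (dl * 1e-4) / (pi * (rr0 * 1e-4) * (rr1 * 1e-4))
      }
      if (area_um2 <= 0) {
        abort("degenerate zero-area compartment",
              class = "dendrofire_discretization_error")
      }
      n_comp <- n_comp + 1L
      comp_parent <- c(comp_parent, parent_comp)
      comp_region <- c(comp_region, names(SWC_STRUCTURES)[
        match(sec$structure[s], SWC_STRUCTURES)])
      comp_x <- c(comp_x, x0 + (lo + hi) / 2)
      comp_len <- c(comp_len, hi - lo)
      comp_area <- c(comp_area, area_um2 * 1e-8)
      g_here <- if (parent_comp == 0L) 0 else
        1e6 / (r_axial / 2 + parent_rhalf)
      g_ax <- c(g_ax, g_here)
      parent_comp <- n_comp
      parent_rhalf <- r_axial / 2
    }
    sec_last_comp[s] <- n_comp
    sec_end_x[s] <- x0 + total
    sec_last_rhalf[s] <- parent_rhalf
  }

  if (n_comp == 0L) {
    abort("no compartments produced", class = "dendrofire_discretization_error")
  }

  comps <- tibble(
    comp = seq_len(n_comp), parent = comp_parent, region = comp_region,
    x_um = comp_x, length_um = comp_len, area_cm2 = comp_area,
    g_ax_us = g_ax
  )
  structure(list(comps = comps, spec = spec, has_soma = has_soma),
            class = "compartment_graph")
}

#' @export
print.compartment_graph <- function(x, ...) {
  cat("<compartment_graph> ", nrow(x$comps), " compartments, total area ",
      signif(sum(x$comps$area_cm2), 4), " cm^2\n", sep = "")
  invisible(x)
}

#' Current-clamp stimulus protocol
#'
#' @param amplitude_na Step amplitude in nA (negative = hyperpolarizing).
#' @param t_start,t_end Step onset and offset in ms.
#' @param duration_ms Total simulated duration in ms.
#' @param target Target compartment: `"soma"` or a compartment index.
#' @return A list of class `stimulus_protocol`.
#' @export
step_protocol <- function(amplitude_na, t_start = 100, t_end = 600,
                          duration_ms = t_end + 100, target = "soma") {
  if (t_end <= t_start) {
    abort("t_end must exceed t_start", class = "dendrofire_argument_error")
  }
  structure(list(segments = tibble(t_start = t_start, t_end = t_end,
                                   amplitude_na = amplitude_na,
                                   target = list(target)),
                 duration_ms = duration_ms),
            class = "stimulus_protocol")
}

resolve_target <- function(graph, target) {
  if (identical(target, "soma")) {
    if (graph$has_soma) return(1L)
    return(1L)  # rootmost compartment of a pure cable
  }
  as.integer(target)
}

#' Integrate the cable equation over a compartment graph
#'
#' Backward-Euler time stepping with a tree-ordered direct solve per step
#' and exact exponential channel-gate updates; unconditionally stable and
#' fully deterministic (identical inputs give bit-identical traces).  A
#' settle period at rest precedes the stimulus and is discarded from the
#' returned trace.
#'
#' @param graph A [discretize()] compartment graph.
#' @param protocol A [step_protocol()] (or list of segment rows).
#' @param dt Time step in ms.
#' @param record Recording site, `"soma"` or compartment index.
#' @param settle_ms Settle-to-rest duration discarded before t = 0.
#' @param passive_only If `TRUE`, all channel densities are zeroed (leak
#'   only), for analytic comparisons.
#' @return A tibble of class `voltage_trace` with columns `t_ms`, `v_mv`;
#'   attributes `dt`, `record`.
#' @export
simulate_cell <- function(graph, protocol, dt = 0.025, record = "soma",
                          settle_ms = 200, passive_only = FALSE) {
  stopifnot(inherits(graph, "compartment_graph"),
            inherits(protocol, "stimulus_protocol"))
  spec <- graph$spec
  comps <- graph$comps
  pass <- spec$passive
  rm_kohm <- rm_at_region_vec(pass, comps$region, comps$x_um)
  g_pas <- 1 / (rm_kohm * 1000)
  dens <- conductance_matrix(spec, graph)
  if (passive_only) dens[] <- 0

  seg <- protocol$segments
  stim <- matrix(0, nrow = nrow(seg), ncol = 4)
  for (i in seq_len(nrow(seg))) {
    stim[i, ] <- c(seg$t_start[i], seg$t_end[i], seg$amplitude_na[i],
                   resolve_target(graph, seg$target[[i]]) - 1L)
  }
  cal <- spec$config$calcium
  rev <- spec$config$reversals
  res <- .simulate_cell_cpp(
    parent = as.integer(comps$parent - 1L), area_cm2 = comps$area_cm2,
    g_pas = g_pas, e_pas = pass$v_rest_mv, cm_uf = pass$cm_uf_cm2,
    g_ax = comps$g_ax_us, dens = dens, stim = stim,
    dt = dt, t_stop = protocol$duration_ms, settle_ms = settle_ms,
    record = resolve_target(graph, record) - 1L, v_init = pass$v_rest_mv,
    e_na = rev$e_na, e_k = rev$e_k, e_h = rev$e_h,
    ca0_mM = cal$ca0_mM, cao_mM = cal$cao_mM,
    ca_gain = cal$gain, ca_tau = cal$tau_ms)
  out <- tibble(t_ms = res$t_ms, v_mv = res$v_mv)
  attr(out, "dt") <- dt
  attr(out, "record") <- record
  class(out) <- c("voltage_trace", class(out))
  out
}

rm_at_region_vec <- function(profile, region, x) {
  out <- numeric(length(region))
  for (rg in unique(region)) {
    sel <- region == rg
    out[sel] <- rm_at(profile, rg, x[sel])
  }
  out
}

#' Write a voltage trace as two-column delimited text
#'
#' @param trace A `voltage_trace`.
#' @param path Output path (`#` metadata header, then `t_ms<TAB>v_mV`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  header <- c("# dendrofire voltage trace",
              sprintf("# dt_ms: %g", attr(trace, "dt")),
              "# columns: t_ms v_mV")
  writeLines(c(header, sprintf("%.6g\t%.9g", trace$t_ms, trace$v_mv)), path)
  invisible(path)
}

#' Read a voltage trace written by [write_trace()]
#' @param path File path.
#' @return A `voltage_trace` tibble.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dt_line <- grep("^# dt_ms:", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(trimws(body[nzchar(body)]), "[[:space:]]+")
  mat <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  out <- tibble(t_ms = mat[, 1], v_mv = mat[, 2])
  attr(out, "dt") <- if (length(dt_line) > 0)
    as.numeric(sub("^# dt_ms: *", "", dt_line[1])) else
      stats::median(diff(out$t_ms))
  class(out) <- c("voltage_trace", class(out))
  out
}
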