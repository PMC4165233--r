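# Passive membrane profile and ion-channel distribution rules.
#
# Passive defaults: Rm = 30 kOhm cm2 in soma and axon; in the dendrites the
# membrane resistance falls sigmoidally with path distance x (um) from the
# soma towards half the somatic value,
#   basal:  Rm(x) = 30 - 15 / (1 + exp((10  - x) / 5 ))
#   apical: Rm(x) = 30 - 15 / (1 + exp((300 - x) / 50))
# Ra = 210 Ohm cm, Cm = 1.2 uF/cm2, resting potential -66 mV.

#' Passive membrane parameter profile
#'
#' @param rm_soma_kohm_cm2 Somatic/axonal specific membrane resistance,
#'   kOhm cm^2.
#' @param ra_ohm_cm Intracellular resistivity, Ohm cm.
#' @param cm_uf_cm2 Specific membrane capacitance, uF/cm^2.
#' @param v_rest_mv Resting membrane potential, mV.
#' @param basal_x_half,basal_slope Midpoint (um) and slope (um) of the
#'   sigmoidal basal Rm decrease.
#' @param apical_x_half,apical_slope Same for the apical tree.
#' @return A list of class `passive_profile`.
#' @export
passive_profile <- function(rm_soma_kohm_cm2 = 30, ra_ohm_cm = 210,
                            cm_uf_cm2 = 1.2, v_rest_mv = -66,
                            basal_x_half = 10, basal_slope = 5,
                            apical_x_half = 300, apical_slope = 50) {
  structure(list(rm_soma_kohm_cm2 = rm_soma_kohm_cm2, ra_ohm_cm = ra_ohm_cm,
                 cm_uf_cm2 = cm_uf_cm2, v_rest_mv = v_rest_mv,
                 basal_x_half = basal_x_half, basal_slope = basal_slope,
                 apical_x_half = apical_x_half, apical_slope = apical_slope),
            class = "passive_profile")
}

#' Membrane resistance at a path distance from the soma
#'
#' Evaluates the position-dependent specific membrane resistance: constant
#' in soma and axon, sigmoidally decreasing with distance in basal and
#' apical dendrites with an asymptote at half the somatic value.
#'
#' @param profile A [passive_profile()].
#' @param region One of `"soma"`, `"axon"`, `"basal"`, `"apical"`.
#' @param x Path distance from the soma in um (vectorised, must be >= 0).
#' @return Rm in kOhm cm^2.
#' @export
rm_at <- function(profile, region, x) {
  stopifnot(inherits(profile, "passive_profile"))
  if (any(x < 0)) {
    abort("path distance x must be non-negative",
          class = "dendrofire_argument_error")
  }
  r0 <- profile$rm_soma_kohm_cm2
  half <- r0 / 2
  switch(region,
    soma = ,
    axon = rep(r0, length(x)),
    basal = r0 - half / (1 + exp((profile$basal_x_half - x) / profile$basal_slope)),
    apical = r0 - half / (1 + exp((profile$apical_x_half - x) / profile$apical_slope)),
    abort(paste0("unknown region: ", region),
          class = "dendrofire_argument_error")
  )
}

CHANNEL_NAMES <- c("naf", "nap", "kdr", "ka", "kd", "fahp", "sahp", "h",
                   "cat", "can", "car", "cal")
REGION_NAMES <- c("soma", "axon", "basal", "apical")

#' Default channel configuration
#'
#' Maximal conductance densities (S/cm^2) per region for the twelve
#' currents of the reduced layer V pyramidal cell model: fast and
#' persistent Na+ (naf, nap); delayed-rectifier, A-type and slowly
#' inactivating K+ (kdr, ka, kd); fast and slow Ca2+-activated K+ (fahp,
#' sahp); hyperpolarization-activated cation current (h); and low- and
#' high-voltage activated Ca2+ currents (cat, can, car, cal).  The shipped
#' densities are this package's own defaults, chosen so that the somatic
#' fast after-depolarization (carried by car/cat/nap) produces an initial
#' burst when the dendritic load is small and regular spiking when it is
#' large, and they satisfy the qualitative ordering constraints of the
#' model class: naf highest in the axon, higher in soma/apical than basal;
#' every K+ current weaker in the apical tree than at the soma; AHP
#' currents concentrated at the soma; apical h-current rising sigmoidally
#' to ten times the somatic density with no such rise in basal dendrites.
#'
#' The non-uniform basal mode scales the listed basal densities linearly
#' down with distance (to a floor fraction); apical h follows
#' g(x) = g_soma * (1 + 9 / (1 + exp((x_half - x)/slope))).
#'
#' @return A list of class `channel_config` (JSON-serialisable, see
#'   [write_channel_config()]).
#' @export
default_channel_config <- function() {
  dens <- list(
    #        soma    axon    basal    apical
    naf  = c(0.060,  0.120,  0.004,   0.009),
    nap  = c(0.0001, 0,      0.00005, 0.00005),
    kdr  = c(0.018,  0.030,  0.003,   0.004),
    ka   = c(0.0055, 0.002,  0.004,   0.002),
    kd   = c(0.0006, 0,      0.0002,  0.0001),
    fahp = c(0.140,  0,      0,       0.001),
    sahp = c(0.006,  0,      0,       0.0005),
    h    = c(0.0001, 0,      0.0001,  0.0001),
    cat  = c(0.0001, 0,      0,       0.00005),
    can  = c(0.0005, 0,      0,       0.0001),
    car  = c(0.0015, 0,      0.002,   0.0001),
    cal  = c(0.0005, 0,      0,       0.00005)
  )
  channels <- purrr::map(dens, function(v) as.list(setNames(v, REGION_NAMES)))
  structure(list(
    channels = channels,
    apical_h = list(shape = "sigmoid10x", x_half = 300, slope = 50),
    nonuniform_basal = list(channels = c("naf", "kdr", "ka"),
                            floor = 0.5, x_scale = 400),
    reversals = list(e_na = 60, e_k = -90, e_h = -30),
    calcium = list(cao_mM = 2, ca0_mM = 1e-4, gain = 0.05, tau_ms = 80)
  ), class = "channel_config")
}

#' Validate the qualitative ordering constraints of a channel configuration
#'
#' Checks the region-wise density orderings the model class prescribes and
#' aborts naming the violated constraint: `naf` axon > soma >= apical >
#' basal; each K+ current (`kdr`, `ka`, `kd`) weaker apically than
#' somatically; `fahp`/`sahp` present at the soma and reduced apically;
#' basal `h` showing no increase over the somatic density.
#'
#' @param config A `channel_config` list.
#' @return The config, invisibly, if valid.
#' @export
validate_channel_config <- function(config) {
  ch <- config$channels
  need <- setdiff(CHANNEL_NAMES, names(ch))
  if (length(need) > 0) {
    abort(paste0("missing channel(s): ", paste(need, collapse = ", ")),
          class = "dendrofire_config_error")
  }
  g <- function(name, region) ch[[name]][[region]]
  checks <- list(
    "g_naf(axon) > g_naf(soma)" = g("naf", "axon") > g("naf", "soma"),
    "g_naf(soma) >= g_naf(apical)" = g("naf", "soma") >= g("naf", "apical"),
    "g_naf(apical) > g_naf(basal)" = g("naf", "apical") > g("naf", "basal"),
    "g_kdr(apical) < g_kdr(soma)" = g("kdr", "apical") < g("kdr", "soma"),
    "g_ka(apical) < g_ka(soma)" = g("ka", "apical") < g("ka", "soma"),
    "g_kd(apical) < g_kd(soma)" = g("kd", "apical") < g("kd", "soma"),
    "g_fahp(soma) > 0" = g("fahp", "soma") > 0,
    "g_sahp(soma) > 0" = g("sahp", "soma") > 0,
    "g_fahp(apical) < g_fahp(soma)" = g("fahp", "apical") < g("fahp", "soma"),
    "g_sahp(apical) < g_sahp(soma)" = g("sahp", "apical") < g("sahp", "soma"),
    "g_h(basal) <= g_h(soma)" = g("h", "basal") <= g("h", "soma")
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("channel configuration violates constraint: ", bad[1L]),
          class = "dendrofire_config_error")
  }
  neg <- unlist(ch)[unlist(ch) < 0]
  if (length(neg) > 0) {
    abort("negative conductance density in configuration",
          class = "dendrofire_config_error")
  }
  invisible(config)
}

#' Write / read a channel configuration as JSON
#'
#' @param config A `channel_config` list.
#' @param path JSON file path.
#' @return `write_channel_config()` returns `path` invisibly;
#'   `read_channel_config()` returns a validated `channel_config`.
#' @export
write_channel_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_channel_config
#' @export
read_channel_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$channels <- purrr::map(cfg$channels, as.list)
  cfg$nonuniform_basal$channels <- as.character(cfg$nonuniform_basal$channels)
  cfg <- structure(cfg, class = "channel_config")
  validate_channel_config(cfg)
  cfg
}

#' Assemble a cell specification
#'
#' Binds a morphology to a passive profile, a channel configuration and a
#' basal distribution mode.  In `"uniform"` mode every basal compartment of
#' a channel receives the configured basal density; in `"nonuniform"` mode
#' the densities of the channels listed in `config$nonuniform_basal` are
#' scaled linearly down with path distance from the soma (to a floor
#' fraction).  Non-basal compartments are identical between the two modes.
#'
#' @param m A morphology.
#' @param basal_mode `"uniform"` or `"nonuniform"`.
#' @param config A `channel_config` (validated on entry).
#' @param passive A [passive_profile()].
#' @return A list of class `cell_spec`.
#' @export
build_cell_spec <- function(m, basal_mode = c("uniform", "nonuniform"),
                            config = default_channel_config(),
                            passive = passive_profile()) {
  stopifnot(inherits(m, "morphology"))
  basal_mode <- match.arg(basal_mode)
  validate_channel_config(config)
  structure(list(morphology = m, passive = passive, config = config,
                 basal_mode = basal_mode),
            class = "cell_spec")
}

# density of `channel` for compartments with given regions and path
# distances; implements the apical h sigmoid and the non-uniform basal rule
density_at <- function(spec, channel, region, x) {
  cfg <- spec$config
  base <- unlist(cfg$channels[[channel]])[region]
  g <- unname(base)
  if (channel == "h") {
    ap <- region == "apical"
    if (any(ap)) {
      g_soma <- cfg$channels$h$soma
      g[ap] <- g_soma * (1 + 9 / (1 + exp((cfg$apical_h$x_half - x[ap]) /
                                            cfg$apical_h$slope)))
    }
  }
  if (spec$basal_mode == "nonuniform" &&
      channel %in% cfg$nonuniform_basal$channels) {
    ba <- region == "basal"
    g[ba] <- g[ba] * pmax(cfg$nonuniform_basal$floor,
                          1 - x[ba] / cfg$nonuniform_basal$x_scale)
  }
  g
}

#' Conductance density matrix for a discretized cell
#'
#' @param spec A [build_cell_spec()] object.
#' @param graph A [discretize()] compartment graph.
#' @return A numeric matrix, compartments by channels (S/cm^2).
#' @export
conductance_matrix <- function(spec, graph) {
  comps <- graph$comps
  mat <- vapply(CHANNEL_NAMES,
                function(ch) density_at(spec, ch, comps$region, comps$x_um),
                numeric(nrow(comps)))
  mat <- matrix(mat, nrow = nrow(comps),
                dimnames = list(NULL, CHANNEL_NAMES))
  mat
}
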