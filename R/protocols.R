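# Measurement protocols: input resistance, input-resistance-normalized
# current step, spike detection and RS/IB/Q labelling.
#
# A response is labelled IB (intrinsic bursting) when the interspike
# interval of the first two spikes is smaller than 20 ms, RS (regular
# spiking) when it is 20 ms or larger, and Q (quiescent) when fewer than
# two spikes occur (the ISI rule is undefined for fewer than two spikes).

#' Measure somatic input resistance
#'
#' Injects a long hyperpolarizing current pulse at the soma and reads the
#' steady-state voltage change at pulse end: Rin = |dV_steady| / |I|.
#' Aborts if the voltage has not converged to steady state at pulse end.
#'
#' @param graph A [discretize()] compartment graph.
#' @param pulse_na Pulse amplitude in nA (default -0.1, hyperpolarizing).
#' @param pulse_ms Pulse duration in ms.
#' @param dt Integration step, ms.
#' @param settle_ms Settle-to-rest duration before the pulse.
#' @param steady_tol Maximum allowed |dV/dt| (mV/ms) over the last 20 ms of
#'   the pulse.
#' @param passive_only Zero all channel densities (analytic checks).
#' @return Input resistance in MOhm.
#' @export
measure_input_resistance <- function(graph, pulse_na = -0.1, pulse_ms = 500,
                                     dt = 0.025, settle_ms = 200,
                                     steady_tol = 0.02,
                                     passive_only = FALSE) {
  if (pulse_na == 0) {
    abort("pulse amplitude must be non-zero",
          class = "dendrofire_argument_error")
  }
  pre <- 20
  prot <- step_protocol(pulse_na, t_start = pre, t_end = pre + pulse_ms,
                        duration_ms = pre + pulse_ms)
  tr <- simulate_cell(graph, prot, dt = dt, settle_ms = settle_ms,
                      passive_only = passive_only)
  v0 <- tr$v_mv[which.min(abs(tr$t_ms - pre))]
  v_end <- tr$v_mv[nrow(tr)]
  tail_win <- tr$t_ms >= pre + pulse_ms - 20
  dvdt <- abs(diff(tr$v_mv[tail_win])) / dt
  if (max(dvdt) > steady_tol) {
    abort(sprintf("voltage not at steady state at pulse end (|dV/dt| = %.3g mV/ms)",
                  max(dvdt)),
          class = "dendrofire_steady_state_error")
  }
  abs(v_end - v0) / abs(pulse_na)
}

#' Input-resistance-normalized step amplitude
#'
#' Scales a reference somatic step so that the initial steady
#' depolarization I * Rin is the same for every cell:
#' `I = factor * rin_control / rin_cell` (mode `"equal-dv"`, the default).
#' Mode `"as-worded"` applies the reciprocal reading,
#' `I = factor * rin_cell / rin_control`.
#'
#' @param rin_cell,rin_control Input resistances in MOhm, positive.
#' @param factor Reference amplitude in nA (default 0.35).
#' @param mode `"equal-dv"` or `"as-worded"`.
#' @return Step amplitude in nA.
#' @export
normalized_step <- function(rin_cell, rin_control, factor = 0.35,
                            mode = c("equal-dv", "as-worded")) {
  mode <- match.arg(mode)
  if (any(c(rin_cell, rin_control) <= 0)) {
    abort("input resistances must be positive",
          class = "dendrofire_argument_error")
  }
  if (mode == "equal-dv") factor * rin_control / rin_cell
  else factor * rin_cell / rin_control
}

#' Detect spikes as threshold crossings
#'
#' Upward crossings of the threshold separated by at least the refractory
#' period; crossing times are linearly interpolated.  A plateau above
#' threshold yields exactly one spike (a new spike requires a downward
#' re-crossing first).
#'
#' @param trace A `voltage_trace` (uniform time grid).
#' @param threshold_mv Detection threshold, mV.
#' @param refractory_ms Minimum separation between spikes, ms.
#' @return Numeric vector of spike times in ms (possibly empty).
#' @export
detect_spikes <- function(trace, threshold_mv = 0, refractory_ms = 2) {
  v <- trace$v_mv; t <- trace$t_ms
  up <- which(v[-length(v)] < threshold_mv & v[-1L] >= threshold_mv)
  if (length(up) == 0L) return(numeric())
  frac <- (threshold_mv - v[up]) / (v[up + 1L] - v[up])
  times <- t[up] + frac * (t[up + 1L] - t[up])
  keep <- numeric()
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory_ms) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  keep
}

#' Classify a spike train as RS, IB or Q
#'
#' @param spike_times Sorted spike times in ms.
#' @param isi_threshold_ms First-ISI threshold separating IB from RS
#'   (strict inequality: first ISI exactly at threshold is RS).
#' @param rin_mohm,injected_na Optional metadata carried into the label.
#' @return A list of class `firing_label` with `category` (`"RS"`, `"IB"`
#'   or `"Q"`), `spike_times_ms`, `first_isi_ms` (NA for Q), `rin_mohm`,
#'   `injected_na`.
#' @export
classify_firing <- function(spike_times, isi_threshold_ms = 20,
                            rin_mohm = NA_real_, injected_na = NA_real_) {
  spike_times <- sort(spike_times)
  if (length(spike_times) < 2L) {
    cat_ <- "Q"; isi <- NA_real_
  } else {
    isi <- spike_times[2L] - spike_times[1L]
    cat_ <- if (isi < isi_threshold_ms) "IB" else "RS"
  }
  structure(list(category = cat_, spike_times_ms = spike_times,
                 first_isi_ms = isi, rin_mohm = rin_mohm,
                 injected_na = injected_na),
            class = "firing_label")
}

#' @export
print.firing_label <- function(x, ...) {
  cat("<firing_label> ", x$category, ": ", length(x$spike_times_ms),
      " spike(s)", sep = "")
  if (!is.na(x$first_isi_ms)) cat(", first ISI ", signif(x$first_isi_ms, 4), " ms", sep = "")
  cat("\n")
  invisible(x)
}

#' Broom-style one-row summary of a firing label
#' @param x A `firing_label`.
#' @param ... Unused.
#' @export
tidy.firing_label <- function(x, ...) {
  tibble(category = x$category, n_spikes = length(x$spike_times_ms),
         first_isi_ms = x$first_isi_ms, rin_mohm = x$rin_mohm,
         injected_na = x$injected_na)
}

#' Full measurement protocol for one cell
#'
#' Runs the study protocol on a cell specification: measure input
#' resistance with a hyperpolarizing pulse, scale the reference step by the
#' control cell's input resistance, depolarize the soma, detect spikes and
#' classify the response.
#'
#' @param spec A [build_cell_spec()] object (or morphology).
#' @param rin_control Control-cell input resistance in MOhm; `NULL` uses
#'   the cell's own Rin (i.e. an unnormalized 0.35 nA step).
#' @param factor Reference step amplitude, nA.
#' @param step_ms Depolarizing step duration, ms.
#' @param max_seg_length Spatial discretization limit, um.
#' @param dt Time step, ms.
#' @param isi_threshold_ms RS/IB boundary on the first ISI.
#' @param normalization Passed to [normalized_step()].
#' @param keep_trace If `TRUE`, attach the somatic trace to the label.
#' @return A `firing_label` (with `rin_mohm` and `injected_na` filled in).
#' @export
firing_response <- function(spec, rin_control = NULL, factor = 0.35,
                            step_ms = 600, max_seg_length = 20, dt = 0.025,
                            isi_threshold_ms = 20,
                            normalization = "equal-dv",
                            keep_trace = FALSE) {
  if (inherits(spec, "morphology")) spec <- build_cell_spec(spec)
  graph <- discretize(spec, max_seg_length = max_seg_length)
  rin <- measure_input_resistance(graph, dt = dt)
  amp <- if (is.null(rin_control)) factor else
    normalized_step(rin, rin_control, factor = factor, mode = normalization)
  prot <- step_protocol(amp, t_start = 20, t_end = 20 + step_ms,
                        duration_ms = 20 + step_ms)
  tr <- simulate_cell(graph, prot, dt = dt)
  spikes <- detect_spikes(tr)
  lab <- classify_firing(spikes, isi_threshold_ms = isi_threshold_ms,
                         rin_mohm = rin, injected_na = amp)
  if (keep_trace) lab$trace <- tr
  lab
}
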