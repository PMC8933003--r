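#' Current density trace
#'
#' Pointwise current divided by membrane capacitance.
#'
#' @param trace A `current_trace`.
#' @return Numeric vector of current density, pA/pF.
#' @export
current_density <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  if (trace$capacitance_pf <= 0) stop("capacitance must be > 0")
  trace$current_pa / trace$capacitance_pf
}

#' Flow-activated transient current measured at its peak
#'
#' The extremum of the current density inside a search window after
#' flow onset, minus the mean density over a baseline window
#' immediately before flow onset. The sign is preserved, so an inward
#' (negative) transient yields a negative peak. The extremum direction
#' defaults to the inward minimum.
#'
#' @param trace A `current_trace` with a `flow_on` marker.
#' @param baseline_window_s Baseline window length before flow onset, s.
#' @param search_window_s Search window length after flow onset, s.
#' @param direction `"min"` (inward peak, default) or `"max"`.
#' @return Peak density change, pA/pF.
#' @export
transient_peak <- function(trace, baseline_window_s = 10,
                           search_window_s = 10,
                           direction = c("min", "max")) {
  stopifnot(inherits(trace, "current_trace"))
  direction <- match.arg(direction)
  on <- trace$markers$flow_on
  if (is.null(on)) stop("trace has no `flow_on` marker")
  stop_if_not_scalar(baseline_window_s, "baseline_window_s", positive = TRUE)
  stop_if_not_scalar(search_window_s, "search_window_s", positive = TRUE)
  t <- trace$time_s
  if (on - baseline_window_s < min(t) || on + search_window_s > max(t)) {
    stop("baseline/search windows extend beyond the trace")
  }
  dens <- current_density(trace)
  base <- mean(dens[t >= on - baseline_window_s & t < on])
  seg <- dens[t >= on & t <= on + search_window_s]
  peak <- if (direction == "min") min(seg) else max(seg)
  peak - base
}

#' Steady-state current density over a contiguous window
#'
#' Arithmetic mean of the current density over `[window_start,
#' window_start + window_len)`. Windows shorter than `min_window_s`
#' (45 s by convention) are rejected.
#'
#' @param trace A `current_trace`.
#' @param window_start_s Window start, s.
#' @param window_len_s Window length, s (>= `min_window_s`).
#' @param min_window_s Minimum acceptable window length, s.
#' @return Mean density, pA/pF.
#' @export
steady_state_current <- function(trace, window_start_s, window_len_s = 45,
                                 min_window_s = 45) {
  stopifnot(inherits(trace, "current_trace"))
  stop_if_not_scalar(window_start_s, "window_start_s", nonneg = TRUE)
  stop_if_not_scalar(window_len_s, "window_len_s", positive = TRUE)
  if (window_len_s < min_window_s) {
    stop(sprintf("steady-state window must cover at least %g s of data",
                 min_window_s))
  }
  t <- trace$time_s
  if (window_start_s < min(t) || window_start_s + window_len_s > max(t)) {
    stop("window extends beyond the trace")
  }
  sel <- t >= window_start_s & t < window_start_s + window_len_s
  mean(current_density(trace)[sel])
}

#' Myogenic tone
#'
#' Pressure-induced constriction as a percentage:
#' `100 * (1 - D_active / D_passive)`, where `D_active` is the active
#' lumen diameter and `D_passive` the diameter in Ca2+-free (EGTA)
#' solution.
#'
#' @param d_active Active arterial diameter, um.
#' @param d_passive Passive (Ca2+-free) diameter, um (> 0).
#' @return Tone in percent.
#' @export
myogenic_tone <- function(d_active, d_passive) {
  if (any(d_passive <= 0)) stop("`d_passive` must be > 0")
  if (any(d_active < 0)) stop("`d_active` must be >= 0")
  100 * (1 - d_active / d_passive)
}

#' Intraluminal flow rate for a target wall shear stress
#'
#' Inverts the Poiseuille wall shear-stress relation
#' `tau = 4 eta Q / (pi r^3)` to the volumetric flow rate
#' `Q = tau pi r^3 / (4 eta)` for a lumen of internal diameter
#' `diameter_um`. Inputs are in the units conventional for myography
#' (dyn/cm^2, um, poise); the result is converted to ul/min.
#'
#' @param tau_dyn_cm2 Target wall shear stress, dyn/cm^2.
#' @param diameter_um Lumen internal diameter, um.
#' @param viscosity_poise Dynamic viscosity, poise (default 0.007,
#'   aqueous physiological salt solution at 37 C).
#' @return Flow rate in ul/min, with a `units` attribute documenting
#'   the conversion.
#' @export
flow_for_shear <- function(tau_dyn_cm2, diameter_um,
                           viscosity_poise = 0.007) {
  if (any(tau_dyn_cm2 <= 0) || any(diameter_um <= 0) ||
      any(viscosity_poise <= 0)) {
    stop("all inputs must be > 0")
  }
  r_cm <- diameter_um / 2 * 1e-4
  q_cm3_s <- tau_dyn_cm2 * pi * r_cm^3 / (4 * viscosity_poise)
  out <- q_cm3_s * 1000 * 60  # cm^3/s -> ul/min
  attr(out, "units") <- "ul/min (tau in dyn/cm^2, r in cm, eta in poise)"
  out
}

#' Value as a percentage of a control value
#'
#' @param value Measured value.
#' @param control Control value (nonzero).
#' @return `100 * value / control`.
#' @export
percent_of_control <- function(value, control) {
  if (any(control == 0)) stop("`control` must be nonzero")
  100 * value / control
}
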