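#' Simulate a flow-response whole-cell current trace
#'
#' Generates the biphasic flow response: baseline current density before
#' flow onset; at flow onset the density jumps by the transient
#' amplitude and relaxes exponentially (time constant `tau_s`) toward
#' baseline plus the sustained shift; after flow offset the density
#' relaxes back to baseline with the same time constant. Gaussian noise
#' is added pointwise and the trace is stored as current (pA) together
#' with the membrane capacitance and event markers.
#'
#' With zero noise the minimum of the density trace minus baseline
#' equals the transient amplitude exactly, and a late in-flow window
#' mean minus baseline equals the sustained shift (up to the
#' exponentially vanishing tail).
#'
#' @param config A [trace_sim_config()] object.
#' @return A `current_trace`: list with `time_s`, `current_pa`,
#'   `capacitance_pf`, `markers` (named list with `flow_on`, `flow_off`)
#'   and `config`.
#' @seealso [current_density()], [transient_peak()],
#'   [steady_state_current()]
#' @export
simulate_current_trace <- function(config) {
  if (!inherits(config, "trace_sim_config")) {
    stop("`config` must be created by trace_sim_config()")
  }
  with_seed(config$seed, {
    dt <- 1 / config$sampling_rate_hz
    time_s <- seq(0, config$duration_s, by = dt)
    dens <- rep(config$baseline_pa_pf, length(time_s))
    on <- time_s >= config$flow_on_s & time_s < config$flow_off_s
    dt_on <- time_s[on] - config$flow_on_s
    decay <- exp(-dt_on / config$tau_s)
    dens[on] <- config$baseline_pa_pf +
      config$transient_amp_pa_pf * decay +
      config$sustained_shift_pa_pf * (1 - decay)
    after <- time_s >= config$flow_off_s
    if (any(after)) {
      level_off <- config$baseline_pa_pf +
        config$transient_amp_pa_pf *
          exp(-(config$flow_off_s - config$flow_on_s) / config$tau_s) +
        config$sustained_shift_pa_pf *
          (1 - exp(-(config$flow_off_s - config$flow_on_s) / config$tau_s))
      dens[after] <- config$baseline_pa_pf +
        (level_off - config$baseline_pa_pf) *
          exp(-(time_s[after] - config$flow_off_s) / config$tau_s)
    }
    if (config$noise_sd_pa_pf > 0) {
      dens <- dens + rnorm(length(dens), sd = config$noise_sd_pa_pf)
    }
    structure(
      list(
        time_s = time_s,
        current_pa = dens * config$capacitance_pf,
        capacitance_pf = config$capacitance_pf,
        markers = list(flow_on = config$flow_on_s,
                       flow_off = config$flow_off_s),
        config = config
      ),
      class = "current_trace"
    )
  })
}

#' Construct a current trace from raw vectors
#'
#' @param time_s Strictly increasing time stamps, s.
#' @param current_pa Current, pA (inward negative).
#' @param capacitance_pf Membrane capacitance, pF.
#' @param markers Named list of event times (e.g. `flow_on`,
#'   `flow_off`), s.
#' @return A `current_trace` object.
#' @export
current_trace <- function(time_s, current_pa, capacitance_pf,
                          markers = list()) {
  if (length(time_s) != length(current_pa)) {
    stop("`time_s` and `current_pa` must have equal length")
  }
  if (any(diff(time_s) <= 0)) stop("`time_s` must be strictly increasing")
  stop_if_not_scalar(capacitance_pf, "capacitance_pf", positive = TRUE)
  structure(
    list(time_s = as.numeric(time_s), current_pa = as.numeric(current_pa),
         capacitance_pf = capacitance_pf, markers = markers),
    class = "current_trace"
  )
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "Current trace: %.1f s at %.0f Hz, C = %g pF\n",
    max(x$time_s), 1 / mean(diff(x$time_s)), x$capacitance_pf))
  if (length(x$markers)) {
    cat("  markers:",
        paste(sprintf("%s = %g s", names(x$markers), unlist(x$markers)),
              collapse = ", "), "\n")
  }
  invisible(x)
}
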