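#' Configuration for the two-channel cluster simulator
#'
#' Defines the generative model for two-color SMLM localization data:
#' cluster centers follow a homogeneous Poisson process in a rectangular
#' ROI, cluster areas are exponentially distributed, a configurable
#' fraction of channel-2 clusters is co-centered with a channel-1
#' partner, localizations are scattered uniformly inside each cluster
#' disk and jittered with Gaussian localization-precision noise, and a
#' uniform Poisson background models nonspecific labeling.
#'
#' Defaults mirror the polycystin cluster measurements in endothelial
#' cells: cluster densities of 2 per um^2, exponential area means of
#' 3702.5 nm^2 (channel 1, PC-1-like) and 2157.1 nm^2 (channel 2,
#' PC-2-like), a colocalized fraction of 0.27, and a localization
#' precision of 27 nm (the reported per-fluorophore precisions were
#' 24.6-29.6 nm).
#'
#' @param roi_width_nm,roi_height_nm ROI dimensions in nm (default
#'   10000 x 10000 nm = 100 um^2).
#' @param density_ch1,density_ch2 Expected cluster densities, clusters
#'   per um^2.
#' @param mean_area_ch1_nm2,mean_area_ch2_nm2 Means of the exponential
#'   cluster-area distributions, nm^2.
#' @param coloc_fraction Fraction of channel-2 clusters co-centered with
#'   a channel-1 cluster, in \[0, 1\].
#' @param coloc_offset_nm Gaussian displacement (sd, nm) between the
#'   centers of colocalized partners; 0 means exactly shared centers.
#' @param locs_per_cluster Mean localizations per cluster (Poisson).
#' @param precision_sd_nm Localization precision (Gaussian jitter sd), nm.
#' @param background_density Uniform background localizations per um^2.
#' @param n_frames Number of camera frames localizations are spread over.
#' @param mean_photons Mean photon count recorded per localization.
#' @param psf_sd_nm Nominal PSF standard deviation recorded per
#'   localization, nm.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return An object of class `sim_config`.
#' @seealso [simulate_localizations()]
#' @export
sim_config <- function(roi_width_nm = 10000, roi_height_nm = 10000,
                       density_ch1 = 2, density_ch2 = 2,
                       mean_area_ch1_nm2 = 3702.5,
                       mean_area_ch2_nm2 = 2157.1,
                       coloc_fraction = 0.27,
                       coloc_offset_nm = 0,
                       locs_per_cluster = 50,
                       precision_sd_nm = 27,
                       background_density = 0,
                       n_frames = 20000,
                       mean_photons = 500,
                       psf_sd_nm = 130,
                       seed = 1L) {
  stop_if_not_scalar(roi_width_nm, "roi_width_nm", positive = TRUE)
  stop_if_not_scalar(roi_height_nm, "roi_height_nm", positive = TRUE)
  stop_if_not_scalar(density_ch1, "density_ch1", nonneg = TRUE)
  stop_if_not_scalar(density_ch2, "density_ch2", nonneg = TRUE)
  stop_if_not_scalar(mean_area_ch1_nm2, "mean_area_ch1_nm2", positive = TRUE)
  stop_if_not_scalar(mean_area_ch2_nm2, "mean_area_ch2_nm2", positive = TRUE)
  stop_if_not_scalar(coloc_fraction, "coloc_fraction", nonneg = TRUE)
  if (coloc_fraction > 1) stop("`coloc_fraction` must be in [0, 1]")
  stop_if_not_scalar(coloc_offset_nm, "coloc_offset_nm", nonneg = TRUE)
  stop_if_not_scalar(locs_per_cluster, "locs_per_cluster", nonneg = TRUE)
  stop_if_not_scalar(precision_sd_nm, "precision_sd_nm", nonneg = TRUE)
  stop_if_not_scalar(background_density, "background_density", nonneg = TRUE)
  stop_if_not_scalar(n_frames, "n_frames", positive = TRUE)
  stop_if_not_scalar(mean_photons, "mean_photons", positive = TRUE)
  stop_if_not_scalar(psf_sd_nm, "psf_sd_nm", positive = TRUE)
  structure(
    list(
      roi_width_nm = roi_width_nm, roi_height_nm = roi_height_nm,
      density_ch1 = density_ch1, density_ch2 = density_ch2,
      mean_area_ch1_nm2 = mean_area_ch1_nm2,
      mean_area_ch2_nm2 = mean_area_ch2_nm2,
      coloc_fraction = coloc_fraction,
      coloc_offset_nm = coloc_offset_nm,
      locs_per_cluster = locs_per_cluster,
      precision_sd_nm = precision_sd_nm,
      background_density = background_density,
      n_frames = as.integer(n_frames),
      mean_photons = mean_photons,
      psf_sd_nm = psf_sd_nm,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Configuration for the raw-frame (camera) simulator
#'
#' Parameters of the pixelated PSF model used to synthesize blinking
#' single-molecule movies: `s` is the PSF standard deviation, `q` the
#' pixel size, `N` the mean photons collected per emitter per on-frame
#' and `b` the background noise per pixel (the per-pixel background is
#' Poisson with mean `b^2`, hence standard deviation `b`). These are the
#' quantities entering the Thompson precision formula.
#'
#' @param positions_nm Two-column matrix of emitter x/y positions (nm).
#' @param fov_nm Length-2 field of view, c(width, height) in nm.
#' @param s_nm PSF standard deviation, nm.
#' @param q_nm Pixel size, nm.
#' @param n_photons Mean photons per emitter per on-frame.
#' @param b_photons Background noise per pixel (sd of the Poisson
#'   background), photons.
#' @param n_frames Number of frames.
#' @param duty_cycle Probability an emitter is on in a given frame,
#'   in (0, 1].
#' @param seed Integer seed.
#' @return An object of class `frame_sim_config`.
#' @seealso [simulate_frames()], [thompson_precision()]
#' @export
frame_sim_config <- function(positions_nm, fov_nm,
                             s_nm = 130, q_nm = 100,
                             n_photons = 500, b_photons = 2,
                             n_frames = 100, duty_cycle = 1,
                             seed = 1L) {
  positions_nm <- as.matrix(positions_nm)
  if (ncol(positions_nm) != 2L) {
    stop("`positions_nm` must have two columns (x, y)")
  }
  if (length(fov_nm) != 2L || any(fov_nm <= 0)) {
    stop("`fov_nm` must be two positive lengths c(width, height)")
  }
  stop_if_not_scalar(s_nm, "s_nm", positive = TRUE)
  stop_if_not_scalar(q_nm, "q_nm", positive = TRUE)
  stop_if_not_scalar(n_photons, "n_photons", nonneg = TRUE)
  stop_if_not_scalar(b_photons, "b_photons", nonneg = TRUE)
  stop_if_not_scalar(n_frames, "n_frames", positive = TRUE)
  stop_if_not_scalar(duty_cycle, "duty_cycle", positive = TRUE)
  if (duty_cycle > 1) stop("`duty_cycle` must be in (0, 1]")
  if (nrow(positions_nm) > 0 &&
      (any(positions_nm[, 1] < 0) || any(positions_nm[, 1] > fov_nm[1]) ||
       any(positions_nm[, 2] < 0) || any(positions_nm[, 2] > fov_nm[2]))) {
    stop("emitter positions must lie inside the field of view")
  }
  structure(
    list(
      positions_nm = positions_nm, fov_nm = as.numeric(fov_nm),
      s_nm = s_nm, q_nm = q_nm, n_photons = n_photons,
      b_photons = b_photons, n_frames = as.integer(n_frames),
      duty_cycle = duty_cycle, seed = as.integer(seed)
    ),
    class = "frame_sim_config"
  )
}

#' Configuration for the three-channel FRET image simulator
#'
#' @param efficiency True FRET efficiency map (matrix in \[0, 1\]), or a
#'   scalar recycled over `dim`.
#' @param donor,acceptor Fluorophore abundance maps (matrices), or
#'   scalars recycled over `dim`.
#' @param dim Image dimensions c(nrow, ncol) used when scalar maps are
#'   given.
#' @param a Acceptor-to-FRET-channel bleed-through coefficient (>= 0).
#' @param d Donor-to-FRET-channel bleed-through coefficient (>= 0).
#' @param noise_sd Additive Gaussian noise sd per channel.
#' @param offsets Per-channel background offsets, named or ordered
#'   c(dd, aa, da).
#' @param seed Integer seed.
#' @return An object of class `fret_sim_config`.
#' @seealso [simulate_fret_images()], [nfret_map()]
#' @export
fret_sim_config <- function(efficiency = 0.25, donor = 100, acceptor = 100,
                            dim = c(64, 64), a = 0.25, d = 0.6,
                            noise_sd = 0, offsets = c(0, 0, 0),
                            seed = 1L) {
  as_map <- function(x, name) {
    if (is.matrix(x)) return(x)
    stop_if_not_scalar(x, name)
    matrix(x, dim[1], dim[2])
  }
  efficiency <- as_map(efficiency, "efficiency")
  donor <- as_map(donor, "donor")
  acceptor <- as_map(acceptor, "acceptor")
  if (!all(dim(donor) == dim(efficiency)) ||
      !all(dim(acceptor) == dim(efficiency))) {
    stop("efficiency, donor and acceptor maps must share dimensions")
  }
  if (any(efficiency < 0 | efficiency > 1)) {
    stop("`efficiency` must lie in [0, 1]")
  }
  if (any(donor < 0) || any(acceptor < 0)) {
    stop("abundance maps must be non-negative")
  }
  stop_if_not_scalar(a, "a", nonneg = TRUE)
  stop_if_not_scalar(d, "d", nonneg = TRUE)
  stop_if_not_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(offsets) != 3L || any(offsets < 0)) {
    stop("`offsets` must be three non-negative values c(dd, aa, da)")
  }
  structure(
    list(
      efficiency = efficiency, donor = donor, acceptor = acceptor,
      a = a, d = d, noise_sd = noise_sd,
      offsets = stats::setNames(as.numeric(offsets), c("dd", "aa", "da")),
      seed = as.integer(seed)
    ),
    class = "fret_sim_config"
  )
}

#' Configuration for the flow-response current-trace simulator
#'
#' Emulates the biphasic whole-cell response of an endothelial cell to
#' the onset of bath flow at a holding potential of -60 mV: a steady
#' baseline inward current, a transient increase in inward current at
#' flow onset that decays exponentially, and a sustained reduction in
#' inward current that persists until flow is switched off. Defaults
#' follow the reported scales: baseline about -5.5 pA/pF, transient
#' about -1.3 pA/pF, and a sustained shift of +4.53 pA/pF (steady state
#' about -0.97 pA/pF).
#'
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param duration_s Trace duration, s.
#' @param baseline_pa_pf Baseline current density, pA/pF (inward
#'   negative).
#' @param transient_amp_pa_pf Amplitude of the flow-onset transient,
#'   pA/pF (negative for an inward transient).
#' @param tau_s Exponential time constant of the transient, s.
#' @param sustained_shift_pa_pf Sustained change in current density
#'   during flow, pA/pF.
#' @param flow_on_s,flow_off_s Flow-onset and flow-offset times, s.
#' @param noise_sd_pa_pf Additive Gaussian noise sd, pA/pF.
#' @param capacitance_pf Membrane capacitance, pF.
#' @param seed Integer seed.
#' @return An object of class `trace_sim_config`.
#' @seealso [simulate_current_trace()], [transient_peak()],
#'   [steady_state_current()]
#' @export
trace_sim_config <- function(sampling_rate_hz = 100, duration_s = 180,
                             baseline_pa_pf = -5.5,
                             transient_amp_pa_pf = -1.3,
                             tau_s = 2,
                             sustained_shift_pa_pf = 4.53,
                             flow_on_s = 60, flow_off_s = 150,
                             noise_sd_pa_pf = 0,
                             capacitance_pf = 10,
                             seed = 1L) {
  stop_if_not_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  stop_if_not_scalar(duration_s, "duration_s", positive = TRUE)
  stop_if_not_scalar(baseline_pa_pf, "baseline_pa_pf")
  stop_if_not_scalar(transient_amp_pa_pf, "transient_amp_pa_pf")
  stop_if_not_scalar(tau_s, "tau_s", positive = TRUE)
  stop_if_not_scalar(sustained_shift_pa_pf, "sustained_shift_pa_pf")
  stop_if_not_scalar(flow_on_s, "flow_on_s", nonneg = TRUE)
  stop_if_not_scalar(flow_off_s, "flow_off_s", nonneg = TRUE)
  stop_if_not_scalar(noise_sd_pa_pf, "noise_sd_pa_pf", nonneg = TRUE)
  stop_if_not_scalar(capacitance_pf, "capacitance_pf", positive = TRUE)
  if (flow_on_s >= flow_off_s || flow_off_s > duration_s) {
    stop("require flow_on_s < flow_off_s <= duration_s")
  }
  structure(
    list(
      sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
      baseline_pa_pf = baseline_pa_pf,
      transient_amp_pa_pf = transient_amp_pa_pf, tau_s = tau_s,
      sustained_shift_pa_pf = sustained_shift_pa_pf,
      flow_on_s = flow_on_s, flow_off_s = flow_off_s,
      noise_sd_pa_pf = noise_sd_pa_pf, capacitance_pf = capacitance_pf,
      seed = as.integer(seed)
    ),
    class = "trace_sim_config"
  )
}
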