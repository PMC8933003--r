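# Shared fixtures: small, fast synthetic inputs built in code.

# A compact two-channel simulation on a 5 x 5 um ROI.
small_sim <- function(seed = 1, ...) {
  simulate_localizations(sim_config(
    roi_width_nm = 5000, roi_height_nm = 5000, seed = seed, ...
  ))
}

# Localization table with a single tight blob of points.
blob_table <- function(cx, cy, n = 50, spread = 15, seed = 1,
                       precision_nm = 0) {
  set.seed(seed)
  data.frame(
    frame = seq_len(n) - 1L,
    x_nm = rnorm(n, cx, spread), y_nm = rnorm(n, cy, spread),
    photons = rep(500, n), sigma_nm = rep(130, n),
    background = rep(2, n), precision_nm = rep(precision_nm, n)
  )
}

# Deterministic (noise-free) single-emitter frame stack built from the
# pixel-integrated Gaussian model itself.
noiseless_stack <- function(x_nm, y_nm, s_nm = 130, q_nm = 100,
                            n_photons = 5000, dim_px = 15,
                            n_frames = 1) {
  s_px <- s_nm / q_nm
  px <- seq_len(dim_px)
  ex <- pnorm((px - x_nm / q_nm) / s_px) -
    pnorm((px - 1 - x_nm / q_nm) / s_px)
  ey <- pnorm((px - y_nm / q_nm) / s_px) -
    pnorm((px - 1 - y_nm / q_nm) / s_px)
  counts <- array(rep(n_photons * outer(ey, ex), n_frames),
                  dim = c(dim_px, dim_px, n_frames))
  structure(
    list(counts = counts, q_nm = q_nm,
         fov_nm = c(dim_px * q_nm, dim_px * q_nm),
         on_matrix = NULL, config = NULL),
    class = "frame_stack"
  )
}
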