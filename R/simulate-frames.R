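#' Simulate a camera frame stack of blinking emitters
#'
#' Each frame contains, for every emitter that is on (Bernoulli with
#' probability `duty_cycle`), a Poisson number of photons with mean `N`,
#' each photon landing at a Gaussian-distributed position (sd `s`)
#' around the emitter and binned into `q`-sized pixels -- equivalent to
#' Poisson sampling of the pixel-integrated Gaussian PSF. Per-pixel
#' background counts are Poisson with mean `b^2`, so the background
#' noise per pixel has standard deviation `b`, the quantity entering
#' [thompson_precision()].
#'
#' @param config A [frame_sim_config()] object.
#' @return A `frame_stack`: list with `counts` (array
#'   `nrow x ncol x n_frames`, photon counts; rows index y, columns x),
#'   `q_nm`, `fov_nm`, `on_matrix` (emitters x frames logical) and
#'   `config`.
#' @examples
#' cfg <- frame_sim_config(cbind(500, 500), fov_nm = c(1000, 1000),
#'                         n_frames = 5, seed = 2)
#' stk <- simulate_frames(cfg)
#' dim(stk$counts)
#' @export
simulate_frames <- function(config) {
  if (!inherits(config, "frame_sim_config")) {
    stop("`config` must be created by frame_sim_config()")
  }
  with_seed(config$seed, {
    q <- config$q_nm
    nx <- max(1L, ceiling(config$fov_nm[1] / q))
    ny <- max(1L, ceiling(config$fov_nm[2] / q))
    n_em <- nrow(config$positions_nm)
    counts <- array(0L, dim = c(ny, nx, config$n_frames))
    on_matrix <- matrix(FALSE, nrow = n_em, ncol = config$n_frames)
    bg_mean <- config$b_photons^2
    for (f in seq_len(config$n_frames)) {
      frame <- if (bg_mean > 0) {
        matrix(rpois(nx * ny, bg_mean), ny, nx)
      } else {
        matrix(0L, ny, nx)
      }
      if (n_em > 0 && config$n_photons > 0) {
        on <- runif(n_em) < config$duty_cycle
        on_matrix[, f] <- on
        for (e in which(on)) {
          nph <- rpois(1L, config$n_photons)
          if (nph == 0) next
          px <- config$positions_nm[e, 1] + rnorm(nph, sd = config$s_nm)
          py <- config$positions_nm[e, 2] + rnorm(nph, sd = config$s_nm)
          ix <- floor(px / q) + 1
          iy <- floor(py / q) + 1
          keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
          if (any(keep)) {
            idx <- (ix[keep] - 1L) * ny + iy[keep]
            hits <- tabulate(idx, nbins = nx * ny)
            frame <- frame + matrix(hits, ny, nx)
          }
        }
      }
      counts[, , f] <- frame
    }
    structure(
      list(counts = counts, q_nm = q, fov_nm = config$fov_nm,
           on_matrix = on_matrix, config = config),
      class = "frame_stack"
    )
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Frame stack: %d frames of %d x %d px (q = %g nm)\n",
              d[3], d[1], d[2], x$q_nm))
  invisible(x)
}
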