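# FFT cross-correlation of two equally sized matrices; returns the
# (dy, dx) shift of `b` relative to `a` in pixels, sub-pixel refined by
# 3-point parabolic interpolation around the correlation peak.
xcorr_shift <- function(a, b, max_shift_px) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  nr <- nrow(a); nc <- ncol(a)
  # admissible circular shifts
  sy <- c(0:max_shift_px, (nr - max_shift_px):(nr - 1))
  sx <- c(0:max_shift_px, (nc - max_shift_px):(nc - 1))
  sub <- cc[sy + 1, sx + 1, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  to_signed <- function(i, n) ifelse(i > n / 2, i - n, i)
  dy <- to_signed(sy[pk[1]], nr)
  dx <- to_signed(sx[pk[2]], nc)
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  at <- function(i, j) cc[(i %% nr) + 1, (j %% nc) + 1]
  dy <- dy + para(at(dy - 1, dx), at(dy, dx), at(dy + 1, dx))
  dx <- dx + para(at(dy0 <- round(dy), dx - 1), at(dy0, dx),
                  at(dy0, dx + 1))
  # shift of b relative to a: b displaced by +d gives peak at -d
  c(dy = -dy, dx = -dx)
}

#' Estimate and subtract sample drift by model-based cross-correlation
#'
#' Localizations are split into time bins; each bin is rendered as a 2D
#' histogram, cross-correlated against the first bin to estimate a
#' rigid 2D shift, and the per-bin shifts (at bin-center frames) are
#' interpolated linearly to every frame and subtracted. The shared
#' underlying structure (the cluster map itself) serves as the
#' correlation model, so no fiducial markers are required.
#'
#' @param table Localization table with `frame`, `x_nm`, `y_nm`.
#' @param time_bin Bin width in frames.
#' @param render_px_nm Render pixel for the correlation images, nm.
#' @param blur_px Gaussian blur (pixels) applied to the rendered bins
#'   before correlation.
#' @param max_shift_nm Largest drift magnitude searched for, nm.
#' @return List with `table` (drift-corrected localizations), `drift`
#'   (data.frame `frame`, `dx_nm`, `dy_nm`: the estimated drift
#'   trajectory that was subtracted) and `bin_shifts` (per-bin
#'   estimates).
#' @export
drift_correct <- function(table, time_bin = 2000, render_px_nm = 50,
                          blur_px = 1, max_shift_nm = 1000) {
  check_localization_table(table)
  stop_if_not_scalar(time_bin, "time_bin", positive = TRUE)
  stop_if_not_scalar(render_px_nm, "render_px_nm", positive = TRUE)
  if (nrow(table) == 0) stop("empty localization table")
  frames <- table$frame
  bin <- floor(frames / time_bin)
  bins <- seq(min(bin), max(bin))
  if (length(bins) < 2) {
    stop("drift correction needs at least 2 time bins with localizations")
  }
  pad <- max_shift_nm
  xr <- range(table$x_nm) + c(-pad, pad)
  yr <- range(table$y_nm) + c(-pad, pad)
  nc <- max(8L, ceiling(diff(xr) / render_px_nm))
  nr <- max(8L, ceiling(diff(yr) / render_px_nm))
  render_bin <- function(sel) {
    m <- matrix(0, nr, nc)
    if (!any(sel)) return(m)
    ix <- pmin(nc, pmax(1, floor((table$x_nm[sel] - xr[1]) / render_px_nm) + 1))
    iy <- pmin(nr, pmax(1, floor((table$y_nm[sel] - yr[1]) / render_px_nm) + 1))
    idx <- (ix - 1L) * nr + iy
    tab <- tabulate(idx, nbins = nr * nc)
    m[] <- tab
    if (blur_px > 0) m <- EBImage::gblur(m, sigma = blur_px)
    m
  }
  ref <- render_bin(bin == bins[1])
  if (sum(ref) == 0) stop("reference (first) time bin has no localizations")
  max_shift_px <- max(2L, ceiling(max_shift_nm / render_px_nm))
  shifts <- matrix(NA_real_, nrow = length(bins), ncol = 2,
                   dimnames = list(NULL, c("dy", "dx")))
  shifts[1, ] <- 0
  for (k in 2:length(bins)) {
    sel <- bin == bins[k]
    if (!any(sel)) {
      warning(sprintf("time bin %d is empty; interpolating through", bins[k]))
      next
    }
    shifts[k, ] <- xcorr_shift(ref, render_bin(sel), max_shift_px)
  }
  # interpolate through empty bins, then per frame
  centers <- (bins + 0.5) * time_bin
  ok <- !is.na(shifts[, 1])
  dy_bin <- approx(centers[ok], shifts[ok, "dy"], xout = centers,
                   rule = 2)$y * render_px_nm
  dx_bin <- approx(centers[ok], shifts[ok, "dx"], xout = centers,
                   rule = 2)$y * render_px_nm
  fr_seq <- seq(min(frames), max(frames))
  interp_extrap <- function(vals) {
    y <- approx(centers, vals, xout = fr_seq, rule = 2)$y
    nb <- length(centers)
    if (nb >= 2) {
      # linear extrapolation beyond the first/last bin centers
      lo <- fr_seq < centers[1]
      hi <- fr_seq > centers[nb]
      s1 <- (vals[2] - vals[1]) / (centers[2] - centers[1])
      s2 <- (vals[nb] - vals[nb - 1]) / (centers[nb] - centers[nb - 1])
      y[lo] <- vals[1] + s1 * (fr_seq[lo] - centers[1])
      y[hi] <- vals[nb] + s2 * (fr_seq[hi] - centers[nb])
    }
    y
  }
  dx_f <- interp_extrap(dx_bin)
  dy_f <- interp_extrap(dy_bin)
  drift <- data.frame(frame = fr_seq, dx_nm = dx_f, dy_nm = dy_f)
  idx <- match(frames, fr_seq)
  corrected <- table
  corrected$x_nm <- table$x_nm - dx_f[idx]
  corrected$y_nm <- table$y_nm - dy_f[idx]
  list(
    table = corrected, drift = drift,
    bin_shifts = data.frame(bin = bins, frame = centers,
                            dx_nm = dx_bin, dy_nm = dy_bin)
  )
}
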