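#' Simulate a three-channel sensitized-emission FRET image set
#'
#' Forms the donor (I_DD), acceptor (I_AA) and FRET (I_DA) channels from
#' abundance maps and a true per-pixel FRET efficiency E: the donor
#' signal is quenched to `donor * (1 - E)`, the acceptor signal is the
#' acceptor abundance, and the FRET channel is the sensitized emission
#' `donor * E` plus linear bleed-through `a` from the acceptor signal
#' and `d` from the donor signal. Channel offsets are then added,
#' followed by additive Gaussian noise.
#'
#' @param config A [fret_sim_config()] object.
#' @return A [fret_image_set()] whose `truth` element stores the
#'   efficiency and abundance maps.
#' @seealso [nfret_map()]
#' @export
simulate_fret_images <- function(config) {
  if (!inherits(config, "fret_sim_config")) {
    stop("`config` must be created by fret_sim_config()")
  }
  with_seed(config$seed, {
    s_dd <- config$donor * (1 - config$efficiency)
    s_aa <- config$acceptor
    s_da <- config$donor * config$efficiency +
      config$a * s_aa + config$d * s_dd
    noise <- function(m) {
      if (config$noise_sd > 0) {
        m + matrix(rnorm(length(m), sd = config$noise_sd), nrow(m))
      } else m
    }
    set <- fret_image_set(
      i_dd = noise(s_dd + config$offsets["dd"]),
      i_aa = noise(s_aa + config$offsets["aa"]),
      i_da = noise(s_da + config$offsets["da"]),
      a = config$a, d = config$d,
      offsets = config$offsets
    )
    set$truth <- list(efficiency = config$efficiency,
                      donor = config$donor, acceptor = config$acceptor)
    set
  })
}

#' Bundle three FRET channels with their calibration
#'
#' @param i_dd Donor-excitation/donor-emission image (matrix).
#' @param i_aa Acceptor-excitation/acceptor-emission image.
#' @param i_da Donor-excitation/acceptor-emission (FRET) image.
#' @param a Acceptor bleed-through coefficient into the FRET channel.
#' @param d Donor bleed-through coefficient into the FRET channel.
#' @param offsets Per-channel background offsets c(dd, aa, da).
#' @return An object of class `fret_image_set`.
#' @export
fret_image_set <- function(i_dd, i_aa, i_da, a = 0, d = 0,
                           offsets = c(0, 0, 0)) {
  i_dd <- as.matrix(i_dd); i_aa <- as.matrix(i_aa); i_da <- as.matrix(i_da)
  if (!all(dim(i_dd) == dim(i_aa)) || !all(dim(i_dd) == dim(i_da))) {
    stop("channel images must share dimensions")
  }
  stop_if_not_scalar(a, "a", nonneg = TRUE)
  stop_if_not_scalar(d, "d", nonneg = TRUE)
  if (length(offsets) != 3L) stop("`offsets` must have three elements")
  structure(
    list(i_dd = i_dd, i_aa = i_aa, i_da = i_da, a = a, d = d,
         offsets = stats::setNames(as.numeric(offsets),
                                   c("dd", "aa", "da"))),
    class = "fret_image_set"
  )
}

#' @export
print.fret_image_set <- function(x, ...) {
  cat(sprintf("FRET image set: %d x %d px, a = %g, d = %g\n",
              nrow(x$i_dd), ncol(x$i_dd), x$a, x$d))
  invisible(x)
}
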