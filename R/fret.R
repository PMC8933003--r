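#' Subtract channel background offsets from a FRET image set
#'
#' Each channel has its stored offset subtracted and is clipped at
#' zero; offsets are zeroed in the returned set. The number of clipped
#' pixels is recorded in the `clipped` attribute.
#'
#' @param set A [fret_image_set()].
#' @return The background-subtracted set.
#' @export
subtract_background <- function(set) {
  stopifnot(inherits(set, "fret_image_set"))
  clipped <- 0L
  sub <- function(img, off) {
    out <- img - off
    clipped <<- clipped + sum(out < 0)
    pmax(out, 0)
  }
  out <- fret_image_set(
    i_dd = sub(set$i_dd, set$offsets["dd"]),
    i_aa = sub(set$i_aa, set$offsets["aa"]),
    i_da = sub(set$i_da, set$offsets["da"]),
    a = set$a, d = set$d, offsets = c(0, 0, 0)
  )
  out$truth <- set$truth
  attr(out, "clipped") <- clipped
  out
}

#' Estimate bleed-through coefficients from single-labeled controls
#'
#' On a donor-only control the FRET channel contains only donor
#' bleed-through, so `d` is the slope of I_DA against I_DD; likewise
#' `a` is the slope of I_DA against I_AA on an acceptor-only control.
#' Slopes are fitted robustly (M-estimation, [MASS::rlm()]) so bright
#' outlier pixels do not bias the calibration.
#'
#' @param donor_only Background-subtracted [fret_image_set()] of a
#'   donor-only specimen.
#' @param acceptor_only Background-subtracted [fret_image_set()] of an
#'   acceptor-only specimen.
#' @return Named vector `c(a, d)`.
#' @export
estimate_bleedthrough <- function(donor_only, acceptor_only) {
  stopifnot(inherits(donor_only, "fret_image_set"),
            inherits(acceptor_only, "fret_image_set"))
  slope <- function(x, y, label) {
    x <- as.vector(x); y <- as.vector(y)
    if (var(x) == 0) {
      stop(sprintf("degenerate %s control: reference channel is constant",
                   label))
    }
    fit <- suppressWarnings(MASS::rlm(y ~ x, maxit = 50))
    unname(coef(fit)[2])
  }
  c(a = slope(acceptor_only$i_aa, acceptor_only$i_da, "acceptor-only"),
    d = slope(donor_only$i_dd, donor_only$i_da, "donor-only"))
}

#' Pixel-wise normalized FRET (Xia method)
#'
#' The sensitized emission is corrected for linear bleed-through of the
#' donor (`d`) and acceptor (`a`) signals and normalized by the
#' geometric mean of the donor and acceptor intensities:
#' \deqn{N\mathrm{-FRET} = \frac{I_{DA} - d\,I_{DD} - a\,I_{AA}}
#'   {\sqrt{I_{DD}\, I_{AA}}} \times 100\%}
#' computed per pixel on a background-subtracted image set. Pixels with
#' `I_DD * I_AA` at or below `eps_rel` times the image maximum of the
#' product are excluded as invalid to avoid division blow-up.
#'
#' @param set Background-subtracted [fret_image_set()] with
#'   coefficients `a` and `d` set (see [estimate_bleedthrough()]).
#' @param mask Optional logical matrix restricting the ROI mean.
#' @param eps_rel Relative validity floor on `I_DD * I_AA`.
#' @return List of class `nfret_result`: `nfret` (matrix, %; `NA`
#'   outside valid pixels), `roi_mean` (% over valid masked pixels),
#'   `valid` (logical matrix), `method` metadata.
#' @export
nfret_map <- function(set, mask = NULL, eps_rel = 1e-12) {
  stopifnot(inherits(set, "fret_image_set"))
  if (any(set$offsets != 0)) {
    stop("offsets are nonzero; apply subtract_background() first")
  }
  prod_im <- set$i_dd * set$i_aa
  eps <- eps_rel * max(prod_im)
  valid <- prod_im > eps
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(valid))) stop("mask must match image size")
  } else {
    mask <- matrix(TRUE, nrow(valid), ncol(valid))
  }
  nf <- matrix(NA_real_, nrow(valid), ncol(valid))
  nf[valid] <- 100 *
    (set$i_da[valid] - set$d * set$i_dd[valid] -
       set$a * set$i_aa[valid]) / sqrt(prod_im[valid])
  use <- valid & mask
  if (!any(use)) {
    warning("no valid pixels; N-FRET undefined")
    roi_mean <- NA_real_
  } else {
    roi_mean <- mean(nf[use])
  }
  structure(
    list(nfret = nf, roi_mean = roi_mean, valid = valid,
         method = list(normalization = "sqrt(I_DD * I_AA)",
                       a = set$a, d = set$d, eps_rel = eps_rel)),
    class = "nfret_result"
  )
}

#' @export
print.nfret_result <- function(x, ...) {
  cat(sprintf("N-FRET: ROI mean %.2f%% over %d valid pixels\n",
              x$roi_mean, sum(x$valid)))
  invisible(x)
}
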