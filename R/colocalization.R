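#' Nearest-neighbor intercentroid distances between two cluster maps
#'
#' For every cluster in `map_a`, the Euclidean distance from its
#' centroid to the closest cluster centroid in `map_b`, together with a
#' histogram and an exponential fit of the distance distribution (the
#' distances between polycystin cluster centers are exponentially
#' distributed in the source data).
#'
#' @param map_a,map_b `cluster_map` objects (A to B direction;
#'   `map_b` must be non-empty).
#' @param bin_nm Histogram bin width, nm.
#' @return List of class `nn_result`: `distances_nm` (one per A
#'   cluster), `mean_nm`, `histogram` (`breaks`, `counts`), `fit`
#'   (exponential fit of the distances).
#' @export
nearest_neighbor_distances <- function(map_a, map_b, bin_nm = 50) {
  stopifnot(inherits(map_a, "cluster_map"), inherits(map_b, "cluster_map"))
  if (nrow(map_b$clusters) == 0) {
    stop("`map_b` has no clusters; nearest-neighbor distance undefined")
  }
  if (nrow(map_a$clusters) == 0) {
    return(structure(list(distances_nm = numeric(0), mean_nm = NaN,
                          histogram = list(breaks = numeric(0),
                                           counts = integer(0)),
                          fit = NULL),
                     class = "nn_result"))
  }
  ax <- map_a$clusters$x_nm; ay <- map_a$clusters$y_nm
  bx <- map_b$clusters$x_nm; by <- map_b$clusters$y_nm
  # vectorized min over the A x B distance matrix, blocked to cap memory
  n_a <- length(ax)
  d <- numeric(n_a)
  block <- max(1L, floor(2e6 / max(1L, length(bx))))
  for (s in seq(1L, n_a, by = block)) {
    idx <- s:min(n_a, s + block - 1L)
    dx2 <- outer(ax[idx], bx, "-")^2
    dy2 <- outer(ay[idx], by, "-")^2
    d[idx] <- sqrt(apply(dx2 + dy2, 1, min))
  }
  breaks <- seq(0, max(d, bin_nm) + bin_nm, by = bin_nm)
  counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  fit <- if (length(d) >= 2) fit_exponential_area(d) else NULL
  structure(
    list(distances_nm = d, mean_nm = mean(d),
         histogram = list(breaks = breaks, counts = counts), fit = fit),
    class = "nn_result"
  )
}

#' @export
print.nn_result <- function(x, ...) {
  cat(sprintf("Nearest-neighbor distances: n = %d, mean = %.1f nm\n",
              length(x$distances_nm), x$mean_nm))
  invisible(x)
}

# Integer label image (vector of length prod(dim)) from a cluster map.
label_image <- function(map) {
  lab <- integer(prod(map$dim))
  for (k in seq_along(map$footprints)) lab[map$footprints[[k]]] <- k
  lab
}

#' Footprint overlap between two cluster maps
#'
#' A cluster in one channel overlaps the other channel when its
#' footprint shares at least `min_shared_px` render pixels with any
#' footprint of the other map. Fractions are reported in both
#' directions together with the list of overlapping pairs. Both maps
#' must live on the same render grid.
#'
#' @param map_a,map_b `cluster_map` objects on a common grid.
#' @param min_shared_px Minimum number of shared render pixels for a
#'   pair to count as overlapping (default 1).
#' @return List of class `overlap_result`: `fraction_a` (A clusters
#'   overlapping B), `fraction_b`, `pairs` (data.frame `id_a`, `id_b`,
#'   `shared_px`), `n_a`, `n_b`, and `criterion` metadata.
#' @export
overlap_fraction <- function(map_a, map_b, min_shared_px = 1) {
  stopifnot(inherits(map_a, "cluster_map"), inherits(map_b, "cluster_map"))
  if (map_a$pixel_nm != map_b$pixel_nm || !all(map_a$dim == map_b$dim) ||
      !isTRUE(all.equal(map_a$roi, map_b$roi))) {
    stop("cluster maps must share the same render grid and ROI")
  }
  stop_if_not_scalar(min_shared_px, "min_shared_px", positive = TRUE)
  n_a <- nrow(map_a$clusters); n_b <- nrow(map_b$clusters)
  pairs <- data.frame(id_a = integer(0), id_b = integer(0),
                      shared_px = integer(0))
  if (n_a > 0 && n_b > 0) {
    lab_b <- label_image(map_b)
    px_a <- unlist(map_a$footprints)
    own_a <- rep(seq_len(n_a), vapply(map_a$footprints, length, integer(1)))
    hit <- lab_b[px_a]
    sel <- hit > 0L
    if (any(sel)) {
      key <- paste(own_a[sel], hit[sel])
      agg <- table(key)
      parts <- strsplit(names(agg), " ", fixed = TRUE)
      pairs <- data.frame(
        id_a = as.integer(vapply(parts, `[`, "", 1L)),
        id_b = as.integer(vapply(parts, `[`, "", 2L)),
        shared_px = as.integer(agg)
      )
      pairs <- pairs[pairs$shared_px >= min_shared_px, , drop = FALSE]
      pairs <- pairs[order(pairs$id_a, pairs$id_b), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  structure(
    list(
      fraction_a = if (n_a) length(unique(pairs$id_a)) / n_a else NaN,
      fraction_b = if (n_b) length(unique(pairs$id_b)) / n_b else NaN,
      pairs = pairs, n_a = n_a, n_b = n_b,
      criterion = list(pixel_nm = map_a$pixel_nm,
                       min_shared_px = min_shared_px)
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap: A->B %.1f%% (n = %d), B->A %.1f%% (n = %d), %d pairs\n",
    100 * x$fraction_a, x$n_a, 100 * x$fraction_b, x$n_b, nrow(x$pairs)))
  invisible(x)
}

#' Costes-style randomization null for cluster overlap
#'
#' Adapts Costes' randomization test to segmented cluster data: in each
#' iteration every cluster footprint of channel B is rigidly translated
#' to a uniformly random in-ROI position (shape and area preserved;
#' placements that would leave the ROI are excluded by construction,
#' which is equivalent to rejecting and resampling them), channel A is
#' held fixed, and the A-to-B overlap fraction is recomputed. The
#' observed overlap is compared against this chance distribution; the
#' one-sided empirical p-value uses the `(k + 1)/(n + 1)` estimator so
#' it can never be exactly zero.
#'
#' @param map_a,map_b `cluster_map` objects on a common grid.
#' @param n_iter Number of randomization iterations (>= 100).
#' @param seed Integer seed for the placement RNG.
#' @param min_shared_px Overlap criterion passed to the same pixel-
#'   sharing rule as [overlap_fraction()].
#' @return List of class `randomization_result`: `observed` (A->B
#'   fraction), `null_fractions` (per iteration), `null_mean`,
#'   `null_sd`, `p_value`, `n_iter`, `seed`.
#' @export
costes_randomize <- function(map_a, map_b, n_iter = 1000, seed = 1L,
                             min_shared_px = 1) {
  stopifnot(inherits(map_a, "cluster_map"), inherits(map_b, "cluster_map"))
  if (n_iter < 100) stop("`n_iter` must be at least 100")
  if (map_a$pixel_nm != map_b$pixel_nm || !all(map_a$dim == map_b$dim)) {
    stop("cluster maps must share the same render grid")
  }
  n_a <- nrow(map_a$clusters); n_b <- nrow(map_b$clusters)
  if (n_a == 0 || n_b == 0) stop("both maps must contain clusters")
  nr <- map_a$dim[1]; nc <- map_a$dim[2]
  observed <- overlap_fraction(map_a, map_b,
                               min_shared_px = min_shared_px)$fraction_a
  lab_a <- label_image(map_a)
  # footprints as offsets relative to their bounding-box corner
  fp_rel <- lapply(map_b$footprints, function(px) {
    r <- (px - 1L) %% nr; c <- (px - 1L) %/% nr
    list(dr = r - min(r), dc = c - min(c),
         h = max(r) - min(r) + 1L, w = max(c) - min(c) + 1L)
  })
  if (any(vapply(fp_rel, function(f) f$h > nr || f$w > nc, logical(1)))) {
    stop("a channel-B cluster is larger than the ROI; cannot randomize")
  }
  null_fractions <- with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      hits <- lapply(fp_rel, function(f) {
        r0 <- sample.int(nr - f$h + 1L, 1L) - 1L
        c0 <- sample.int(nc - f$w + 1L, 1L) - 1L
        lab_a[(f$dc + c0) * nr + (f$dr + r0) + 1L]
      })
      if (min_shared_px <= 1) {
        ids <- unique(unlist(lapply(hits, function(h) h[h > 0L])))
      } else {
        ids <- unique(unlist(lapply(hits, function(h) {
          shared <- tabulate(h[h > 0L], nbins = n_a)
          which(shared >= min_shared_px)
        })))
      }
      length(ids) / n_a
    }, numeric(1))
  })
  p <- (1 + sum(null_fractions >= observed)) / (n_iter + 1)
  structure(
    list(observed = observed, null_fractions = null_fractions,
         null_mean = mean(null_fractions), null_sd = sd(null_fractions),
         p_value = p, n_iter = n_iter, seed = as.integer(seed)),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "Costes randomization: observed %.1f%%, null %.2f%% +/- %.2f%% (%d iter), p = %.4g\n",
    100 * x$observed, 100 * x$null_mean, 100 * x$null_sd, x$n_iter,
    x$p_value))
  invisible(x)
}

#' Pearson correlation between two images
#'
#' Standard product-moment correlation over the (optionally masked)
#' pixels, as used for pixel colocalization of structured-illumination
#' image pairs.
#'
#' @param img1,img2 Numeric matrices of equal dimensions.
#' @param mask Optional logical matrix selecting pixels.
#' @return Pearson r in \[-1, 1\]; `NA` with a warning when either
#'   image has zero variance over the mask.
#' @export
pearson_coefficient <- function(img1, img2, mask = NULL) {
  img1 <- as.matrix(img1); img2 <- as.matrix(img2)
  if (!all(dim(img1) == dim(img2))) stop("images must share dimensions")
  sel <- if (is.null(mask)) rep(TRUE, length(img1)) else {
    if (!all(dim(mask) == dim(img1))) stop("mask must match image size")
    as.vector(mask)
  }
  x <- img1[sel]; y <- img2[sel]
  if (length(x) < 2) stop("need at least 2 masked pixels")
  if (var(x) == 0 || var(y) == 0) {
    warning("zero variance over the mask; Pearson r undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Manders overlap coefficients
#'
#' `M1` is the fraction of channel-1 intensity (over pixels above `t1`)
#' residing in pixels where channel 2 exceeds `t2`; `M2` is the
#' symmetric quantity. Thresholds default to 0.
#'
#' @param img1,img2 Numeric matrices of equal dimensions.
#' @param t1,t2 Intensity thresholds (>= 0).
#' @return Named vector `c(M1, M2)` in \[0, 1\]; a coefficient is `NA`
#'   with a warning when its denominator is zero.
#' @export
manders_coefficients <- function(img1, img2, t1 = 0, t2 = 0) {
  img1 <- as.matrix(img1); img2 <- as.matrix(img2)
  if (!all(dim(img1) == dim(img2))) stop("images must share dimensions")
  stop_if_not_scalar(t1, "t1", nonneg = TRUE)
  stop_if_not_scalar(t2, "t2", nonneg = TRUE)
  one <- function(num_img, cond_img, tn, tc) {
    above <- num_img > tn
    den <- sum(num_img[above])
    if (den == 0) {
      warning("all-zero denominator; Manders coefficient undefined")
      return(NA_real_)
    }
    sum(num_img[above & cond_img > tc]) / den
  }
  c(M1 = one(img1, img2, t1, t2), M2 = one(img2, img1, t2, t1))
}
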