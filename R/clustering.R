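#' Render a localization table as an intensity image
#'
#' 2D histogram of localizations at `pixel_nm`, optionally blurred with
#' a Gaussian of sd `blur_nm`. The coordinate convention is origin at
#' the ROI top-left, x to the right (columns), y down (rows), with
#' pixel `i` covering the half-open interval `[i*pixel_nm,
#' (i+1)*pixel_nm)`. Total counts are conserved before the blur, and the
#' normalized blur kernel conserves them away from the image border.
#'
#' @param table Localization table.
#' @param pixel_nm Render pixel size, nm.
#' @param blur_nm Gaussian blur sd, nm (0 = none).
#' @param roi ROI as c(xmin, xmax, ymin, ymax) nm; default snugly fits
#'   the data.
#' @return A `density_map`: list with `img` (matrix, rows = y), `pixel_nm`,
#'   `roi`, `blur_nm`.
#' @export
render_map <- function(table, pixel_nm = 10, blur_nm = 0, roi = NULL) {
  check_localization_table(table)
  stop_if_not_scalar(pixel_nm, "pixel_nm", positive = TRUE)
  stop_if_not_scalar(blur_nm, "blur_nm", nonneg = TRUE)
  if (is.null(roi)) {
    roi <- if (nrow(table)) {
      c(0, max(table$x_nm) + pixel_nm, 0, max(table$y_nm) + pixel_nm)
    } else {
      c(0, pixel_nm, 0, pixel_nm)
    }
  }
  nc <- max(1L, ceiling((roi[2] - roi[1]) / pixel_nm))
  nr <- max(1L, ceiling((roi[4] - roi[3]) / pixel_nm))
  img <- matrix(0, nr, nc)
  if (nrow(table)) {
    ix <- floor((table$x_nm - roi[1]) / pixel_nm) + 1
    iy <- floor((table$y_nm - roi[3]) / pixel_nm) + 1
    keep <- ix >= 1 & ix <= nc & iy >= 1 & iy <= nr
    if (any(keep)) {
      img[] <- tabulate((ix[keep] - 1L) * nr + iy[keep], nbins = nr * nc)
    }
  }
  raw <- img
  if (blur_nm > 0) img <- EBImage::gblur(img, sigma = blur_nm / pixel_nm)
  structure(
    list(img = img, raw = raw, pixel_nm = pixel_nm, roi = roi,
         blur_nm = blur_nm),
    class = "density_map"
  )
}

# 8-connected component labeling of a logical mask, igraph-backed.
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(fg)) return(lab)
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L
  occ <- logical(nr * nc); occ[fg] <- TRUE
  offs <- cbind(dr = c(-1, -1, -1, 0), dc = c(-1, 0, 1, -1))
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    r2 <- row + offs[k, "dr"]; c2 <- col + offs[k, "dc"]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- (c2 - 1L) * nr + r2
    ok[ok] <- occ[nb[ok]]
    edges[[k]] <- cbind(fg[ok], nb[ok])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    cbind(match(e[, 1], fg), match(e[, 2], fg)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

#' Segment localization data into surface clusters
#'
#' The table is rendered and blurred ([render_map()]), thresholded at
#' `threshold` localization-equivalents (multiples of the peak produced
#' by a single blurred localization), and the resulting mask is broken
#' into objects -- by a seeded watershed on the blurred density when
#' `split_touching = TRUE` (the default; separates precision-broadened
#' blobs that merely touch) or by plain 8-connected components
#' otherwise. Localizations are assigned to objects through their
#' pixel; objects with fewer than `min_locs` member localizations are
#' discarded.
#'
#' Each cluster's centroid is the mean of its member localization
#' coordinates. Its area is estimated from the second moments of the
#' member localizations with the known localization precision variance
#' subtracted (disk-equivalent area `4*pi*(var - precision^2)`), which
#' removes the precision broadening that would otherwise dominate the
#' thresholded footprint; the reported footprint is the corresponding
#' disk rasterized on the render grid (`footprint = "corrected_disk"`),
#' or the raw mask pixels of the object (`footprint = "raw"`). In both
#' modes the cluster area equals footprint pixel count times
#' `pixel_nm^2`.
#'
#' @param table Localization table; a `precision_nm` column, when
#'   present, supplies the precision correction.
#' @param pixel_nm Render pixel size, nm.
#' @param blur_nm Render blur sd, nm.
#' @param threshold Detection threshold in localization-equivalents.
#' @param min_locs Minimum member localizations per cluster.
#' @param roi ROI c(xmin, xmax, ymin, ymax) nm; defaults to a snug fit.
#' @param split_touching Separate touching blobs by watershed.
#' @param watershed_tol Watershed tolerance, localization-equivalents:
#'   shallower secondary peaks are merged into their neighbor.
#' @param refine_mixture After image-domain segmentation, re-examine
#'   each object's member localizations with a Gaussian-mixture model
#'   selection (spherical components, BIC over 1-3 components,
#'   `mclust`) and split objects whose point pattern is better
#'   explained by several components -- this resolves clusters whose
#'   precision-broadened density blobs have already fused below the
#'   image-domain resolution limit. Splits leaving any component with
#'   fewer than `min_locs` members are not applied; only active in
#'   `"corrected_disk"` footprint mode.
#' @param footprint `"corrected_disk"` (default) or `"raw"`.
#' @return A `cluster_map`: list with `pixel_nm`, `roi`, `dim`,
#'   `clusters` (data.frame `id`, `x_nm`, `y_nm`, `area_nm2`, `n_locs`),
#'   `footprints` (list of pixel linear indices into the render grid)
#'   and `meta` (segmentation parameters).
#' @export
segment_clusters <- function(table, pixel_nm = 10, blur_nm = 20,
                             threshold = 1, min_locs = 3, roi = NULL,
                             split_touching = TRUE, watershed_tol = 2,
                             refine_mixture = TRUE,
                             footprint = c("corrected_disk", "raw")) {
  footprint <- match.arg(footprint)
  check_localization_table(table)
  stop_if_not_scalar(min_locs, "min_locs", positive = TRUE)
  dm <- render_map(table, pixel_nm = pixel_nm, blur_nm = blur_nm, roi = roi)
  roi <- dm$roi
  nr <- nrow(dm$img); nc <- ncol(dm$img)
  unit <- impulse_peak(blur_nm / pixel_nm)
  mask <- dm$img >= threshold * unit
  empty <- cluster_map(
    clusters = data.frame(id = integer(0), x_nm = numeric(0),
                          y_nm = numeric(0), area_nm2 = numeric(0),
                          n_locs = integer(0)),
    footprints = list(), pixel_nm = pixel_nm, roi = roi,
    dim = c(nr, nc),
    meta = list(blur_nm = blur_nm, threshold = threshold,
                min_locs = min_locs, split_touching = split_touching,
                footprint = footprint)
  )
  if (nrow(table) == 0 || !any(mask)) return(empty)
  lab <- if (split_touching) {
    w <- EBImage::watershed(dm$img * mask, tolerance = watershed_tol * unit,
                            ext = 1)
    matrix(as.integer(w), nr, nc)
  } else {
    label_components_8(mask)
  }
  # assign localizations to objects via their render pixel
  ix <- floor((table$x_nm - roi[1]) / pixel_nm) + 1
  iy <- floor((table$y_nm - roi[3]) / pixel_nm) + 1
  inside <- ix >= 1 & ix <= nc & iy >= 1 & iy <= nr
  loc_lab <- integer(nrow(table))
  loc_lab[inside] <- lab[(ix[inside] - 1L) * nr + iy[inside]]
  prec2_all <- if ("precision_nm" %in% names(table)) {
    table$precision_nm^2
  } else {
    rep(0, nrow(table))
  }
  if (refine_mixture && footprint == "corrected_disk") {
    loc_lab <- refine_labels_gmm(table$x_nm, table$y_nm, loc_lab,
                                 min_locs, prec2_all)
  }
  counts <- tabulate(loc_lab[loc_lab > 0], nbins = max(loc_lab))
  keep <- which(counts >= min_locs)
  if (!length(keep)) return(empty)
  prec2 <- prec2_all
  n_keep <- length(keep)
  cx <- cy <- raw_area <- p2m <- numeric(n_keep)
  n_mem <- integer(n_keep)
  for (k in seq_len(n_keep)) {
    sel <- which(loc_lab == keep[k])
    n_mem[k] <- length(sel)
    cx[k] <- mean(table$x_nm[sel]); cy[k] <- mean(table$y_nm[sel])
    v_obs <- clipped_moment_variance(table$x_nm[sel], table$y_nm[sel])
    p2m[k] <- mean(prec2[sel])
    raw_area[k] <- 4 * pi * (v_obs - p2m[k])
  }
  area_est <- if (footprint == "corrected_disk") {
    eb_area(raw_area, n_mem, mean(p2m), pixel_nm)
  } else {
    raw_area
  }
  clusters <- vector("list", n_keep)
  footprints <- vector("list", n_keep)
  for (k in seq_len(n_keep)) {
    fp <- if (footprint == "corrected_disk") {
      disk_pixels(cx[k], cy[k], sqrt(area_est[k] / pi), roi, pixel_nm,
                  nr, nc)
    } else {
      which(lab == keep[k])
    }
    footprints[[k]] <- fp
    clusters[[k]] <- data.frame(
      id = k, x_nm = cx[k], y_nm = cy[k],
      area_nm2 = length(fp) * pixel_nm^2, n_locs = n_mem[k]
    )
  }
  map <- cluster_map(
    clusters = do.call(rbind, clusters), footprints = footprints,
    pixel_nm = pixel_nm, roi = roi, dim = c(nr, nc),
    meta = list(blur_nm = blur_nm, threshold = threshold,
                min_locs = min_locs, split_touching = split_touching,
                footprint = footprint)
  )
  if (footprint == "corrected_disk") resolve_footprint_overlaps(map) else map
}

# Mixture-model refinement of object labels: for each labeled object
# with enough members, select the number of spherical Gaussian
# components (1-3) by BIC; when several components win and every
# component keeps >= min_locs members, the object is split along the
# component classification. Image-domain watershed cannot separate
# clusters whose blurred blobs have fused into a single peak; the
# point pattern still carries the information, which is what the
# mixture criterion exploits.
refine_labels_gmm <- function(x, y, loc_lab, min_locs, prec2 = NULL,
                              min_sep_ratio = 2.8) {
  if (is.null(prec2)) prec2 <- rep(0, length(x))
  n_lab <- max(loc_lab)
  next_id <- n_lab
  for (id in seq_len(n_lab)) {
    sel <- which(loc_lab == id)
    if (length(sel) < 2 * min_locs) next
    fit <- tryCatch(
      Mclust(cbind(x[sel], y[sel]), G = 1:3,
             modelNames = c("EII", "VII"), verbose = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$G <= 1) next
    sizes <- tabulate(fit$classification, nbins = fit$G)
    # a genuine multi-cluster object has comparably sized components; a
    # small peeled-off component is usually the stray tail of a
    # neighbor, not a separate cluster
    if (any(sizes < pmax(min_locs, 0.2 * length(sel)))) next
    # accept the split only when every pair of components is separated
    # by clearly more than a single uniform disk could produce when
    # mis-modeled as a mixture (that artifact gives a separation of
    # about 2.1 component-sd units; genuine cluster pairs give >= 4)
    mu <- fit$parameters$mean
    s2 <- fit$parameters$variance$sigmasq
    if (length(s2) == 1L) s2 <- rep(s2, fit$G)
    p2 <- mean(prec2[sel])
    ok <- TRUE
    for (i in seq_len(fit$G - 1)) {
      for (j in (i + 1):fit$G) {
        d <- sqrt(sum((mu[, i] - mu[, j])^2))
        spread <- sqrt(max(mean(s2[c(i, j)]) - p2, 100))
        if (d <= min_sep_ratio * spread) ok <- FALSE
      }
    }
    if (!ok) next
    for (g in 2:fit$G) {
      next_id <- next_id + 1L
      loc_lab[sel[fit$classification == g]] <- next_id
    }
  }
  loc_lab
}

# Mean per-axis positional variance of a point cluster, made robust to
# stray members (e.g. tail localizations of a neighboring cluster
# captured by the segmentation) by iterative sigma-clipping: points
# with squared radial distance beyond the 99.5% chi-squared(2df)
# quantile of the current variance estimate are dropped and the
# variance recomputed. The known truncation factor of that cut under a
# bivariate Gaussian (0.9734) is divided back out.
clipped_moment_variance <- function(x, y, n_iter = 3) {
  if (length(x) < 2) return(0)
  cut <- stats::qchisq(0.995, df = 2)
  trunc_factor <- {
    c2 <- cut / 2
    (1 - (1 + c2) * exp(-c2)) / (1 - exp(-c2))
  }
  keep <- rep(TRUE, length(x))
  v <- NA_real_
  for (i in seq_len(n_iter)) {
    if (sum(keep) < 2) break
    mx <- mean(x[keep]); my <- mean(y[keep])
    v <- (var(x[keep]) + var(y[keep])) / 2 / trunc_factor
    new_keep <- (x - mx)^2 + (y - my)^2 <= cut * v
    if (all(new_keep == keep)) break
    keep <- new_keep
  }
  max(v, 0)
}

# Empirical-Bayes cluster-area estimator. The raw moment area is
# unbiased but noisy (sd tau ~ area-scale for a few dozen member
# localizations); truncating it at zero would turn that symmetric
# noise into a positive bias on small clusters. Instead the raw value
# is treated as a Gaussian measurement of the true area under an
# exponential(mu) prior on areas; the posterior mean
#   m + tau * phi(m/tau) / Phi(m/tau),  m = raw - tau^2/mu
# is strictly positive and aggregate-unbiased (its marginal mean is
# mu). mu is estimated from the raw areas of the map itself, and tau
# is computed from the map-typical cluster variance rather than each
# cluster's own noisy variance -- using the latter correlates tau with
# the measurement error and systematically over-shrinks.
eb_area <- function(raw, n_mem, prec2_mean, pixel_nm) {
  if (!length(raw)) return(raw)
  mu <- mean(raw)
  if (!is.finite(mu) || mu <= 0) mu <- pixel_nm^2
  v_typ <- mu / (4 * pi) + prec2_mean
  tau <- 4 * pi * v_typ / sqrt(pmax(n_mem - 1, 1))
  m <- raw - tau^2 / mu
  z <- ifelse(tau > 0, m / tau, Inf)
  out <- ifelse(
    tau > 0,
    m + tau * exp(stats::dnorm(z, log = TRUE) -
                    stats::pnorm(z, log.p = TRUE)),
    pmax(raw, pixel_nm^2)
  )
  pmax(out, 1e-6)
}

# Pixel linear indices (rows = y) of a disk rasterized on the render
# grid: pixels whose centers fall inside the disk, never empty (the
# centroid pixel is always included), clipped to the grid.
disk_pixels <- function(cx, cy, radius, roi, pixel_nm, nr, nc) {
  cxp <- (cx - roi[1]) / pixel_nm
  cyp <- (cy - roi[3]) / pixel_nm
  rp <- radius / pixel_nm
  jr <- max(1L, floor(cxp - rp) + 1L):min(nc, ceiling(cxp + rp) + 1L)
  ir <- max(1L, floor(cyp - rp) + 1L):min(nr, ceiling(cyp + rp) + 1L)
  xs <- jr - 0.5; ys <- ir - 0.5
  d2 <- outer((ys - cyp)^2, (xs - cxp)^2, "+")
  hit <- which(d2 <= rp^2)
  if (!length(hit)) {
    j0 <- min(nc, max(1L, floor(cxp) + 1L))
    i0 <- min(nr, max(1L, floor(cyp) + 1L))
    return((j0 - 1L) * nr + i0)
  }
  i_idx <- ir[(hit - 1L) %% length(ir) + 1L]
  j_idx <- jr[(hit - 1L) %/% length(ir) + 1L]
  (j_idx - 1L) * nr + i_idx
}

# Enforce disjoint footprints within a map: a pixel claimed by several
# clusters is kept by the one whose centroid is nearest.
resolve_footprint_overlaps <- function(map) {
  all_px <- unlist(map$footprints)
  if (!length(all_px) || !anyDuplicated(all_px)) return(map)
  owner <- rep(seq_along(map$footprints),
               vapply(map$footprints, length, integer(1)))
  nr <- map$dim[1]
  px_x <- ((all_px - 1L) %/% nr + 0.5) * map$pixel_nm + map$roi[1]
  px_y <- ((all_px - 1L) %% nr + 0.5) * map$pixel_nm + map$roi[3]
  d2 <- (px_x - map$clusters$x_nm[owner])^2 +
    (px_y - map$clusters$y_nm[owner])^2
  ord <- order(all_px, d2)
  first <- !duplicated(all_px[ord])
  keep_px <- all_px[ord][first]
  keep_owner <- owner[ord][first]
  map$footprints <- lapply(seq_along(map$footprints), function(k) {
    sort(keep_px[keep_owner == k])
  })
  map$clusters$area_nm2 <-
    vapply(map$footprints, length, integer(1)) * map$pixel_nm^2
  map
}

#' Construct a cluster map directly
#'
#' Low-level constructor used by [segment_clusters()] and by tests;
#' validates the invariants (areas > 0, centroids inside the ROI).
#'
#' @param clusters data.frame with `id`, `x_nm`, `y_nm`, `area_nm2`,
#'   `n_locs`.
#' @param footprints List (one per cluster) of pixel linear indices into
#'   the render grid (rows = y, column-major).
#' @param pixel_nm Render pixel size, nm.
#' @param roi ROI c(xmin, xmax, ymin, ymax), nm.
#' @param dim Render grid dimensions c(nrow, ncol).
#' @param meta Free-form metadata list.
#' @return A `cluster_map` object.
#' @export
cluster_map <- function(clusters, footprints, pixel_nm, roi, dim,
                        meta = list()) {
  if (nrow(clusters) != length(footprints)) {
    stop("one footprint per cluster required")
  }
  if (nrow(clusters)) {
    if (any(clusters$area_nm2 <= 0)) stop("cluster areas must be > 0")
    if (any(clusters$x_nm < roi[1] | clusters$x_nm > roi[2] |
            clusters$y_nm < roi[3] | clusters$y_nm > roi[4])) {
      stop("cluster centroids must lie inside the ROI")
    }
  }
  structure(
    list(pixel_nm = pixel_nm, roi = as.numeric(roi),
         dim = as.integer(dim), clusters = clusters,
         footprints = footprints, meta = meta),
    class = "cluster_map"
  )
}

#' Build a cluster map from disk-shaped clusters
#'
#' Convenience constructor that rasterizes disks of given centers and
#' areas onto a render grid -- the natural bridge from simulation
#' ground truth (or any parametric cluster description) to the
#' footprint-based colocalization operations.
#'
#' @param centers_nm Two-column matrix of disk centers (x, y), nm.
#' @param areas_nm2 Disk areas, nm^2.
#' @param roi ROI c(xmin, xmax, ymin, ymax), nm.
#' @param pixel_nm Render pixel size, nm.
#' @param n_locs Optional member counts (bookkeeping only).
#' @return A `cluster_map`.
#' @export
cluster_map_from_disks <- function(centers_nm, areas_nm2, roi,
                                   pixel_nm = 10, n_locs = NULL) {
  centers_nm <- as.matrix(centers_nm)
  if (nrow(centers_nm) != length(areas_nm2)) {
    stop("one area per center required")
  }
  nr <- max(1L, ceiling((roi[4] - roi[3]) / pixel_nm))
  nc <- max(1L, ceiling((roi[2] - roi[1]) / pixel_nm))
  footprints <- lapply(seq_along(areas_nm2), function(k) {
    disk_pixels(centers_nm[k, 1], centers_nm[k, 2],
                sqrt(areas_nm2[k] / pi), roi, pixel_nm, nr, nc)
  })
  clusters <- data.frame(
    id = seq_along(areas_nm2),
    x_nm = if (length(areas_nm2)) centers_nm[, 1] else numeric(0),
    y_nm = if (length(areas_nm2)) centers_nm[, 2] else numeric(0),
    area_nm2 = vapply(footprints, length, integer(1)) * pixel_nm^2,
    n_locs = if (is.null(n_locs)) {
      rep(NA_integer_, length(areas_nm2))
    } else {
      as.integer(n_locs)
    }
  )
  resolve_footprint_overlaps(cluster_map(
    clusters = clusters, footprints = footprints, pixel_nm = pixel_nm,
    roi = roi, dim = c(nr, nc), meta = list(footprint = "disk")
  ))
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf(
    "Cluster map: %d clusters on a %d x %d grid (%g nm px)\n",
    nrow(x$clusters), x$dim[1], x$dim[2], x$pixel_nm))
  if (nrow(x$clusters)) {
    cat(sprintf("  density %.3f /um^2, mean area %.0f nm^2\n",
                cluster_density(x), mean(x$clusters$area_nm2)))
  }
  invisible(x)
}

#' Cluster density of a cluster map
#'
#' @param map A `cluster_map`.
#' @return Clusters per um^2 (count divided by ROI area).
#' @export
cluster_density <- function(map) {
  stopifnot(inherits(map, "cluster_map"))
  area_um2 <- (map$roi[2] - map$roi[1]) * (map$roi[4] - map$roi[3]) / 1e6
  if (area_um2 <= 0) stop("ROI area must be > 0")
  nrow(map$clusters) / area_um2
}

#' Maximum-likelihood exponential fit of cluster areas
#'
#' For an exponential distribution the ML estimate of the mean is the
#' sample mean; an approximate 95% CI follows from the normal
#' approximation `mean * (1 +/- 1.96 / sqrt(n))`. The Kolmogorov-
#' Smirnov statistic against the fitted exponential is reported as a
#' goodness-of-fit measure.
#'
#' @param x A `cluster_map`, or a numeric vector of areas/distances.
#' @return List of class `exponential_fit`: `mean`, `ci` (length 2),
#'   `n`, `ks_statistic`.
#' @export
fit_exponential_area <- function(x) {
  areas <- if (inherits(x, "cluster_map")) x$clusters$area_nm2 else x
  areas <- as.numeric(areas)
  if (length(areas) < 2) stop("need at least 2 observations")
  if (any(areas < 0)) stop("areas must be non-negative")
  m <- mean(areas)
  n <- length(areas)
  ks <- suppressWarnings(
    ks.test(areas, "pexp", rate = 1 / m)$statistic
  )
  structure(
    list(mean = m, ci = m * c(1 - 1.96 / sqrt(n), 1 + 1.96 / sqrt(n)),
         n = n, ks_statistic = unname(ks)),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential fit: mean %.1f (95%% CI %.1f-%.1f, n = %d), KS D = %.3f\n",
    x$mean, x$ci[1], x$ci[2], x$n, x$ks_statistic))
  invisible(x)
}
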