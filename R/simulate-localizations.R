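#' Simulate two-channel SMLM localization tables with ground truth
#'
#' Draws cluster centers from a homogeneous Poisson process in the ROI,
#' cluster areas from exponential distributions, co-centers a
#' `coloc_fraction` subset of channel-2 clusters with distinct
#' channel-1 partners, scatters localizations uniformly inside each
#' cluster disk, jitters them with Gaussian localization-precision
#' noise, and adds uniform background localizations. Every generated
#' cluster and the cluster/background assignment of every localization
#' are recorded in the returned ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_localizations` with elements `ch1` and
#'   `ch2` (localization tables: columns `frame`, `x_nm`, `y_nm`,
#'   `photons`, `sigma_nm`, `background`, `precision_nm`), `truth` (a
#'   `ground_truth` object) and `config`.
#'
#' The ground truth holds `clusters` (data.frame with `channel`, `id`,
#' `x_nm`, `y_nm`, `area_nm2`, `n_locs`, `partner_id`; partner ids
#' cross-reference the other channel, `NA` when unpaired) and
#' `assignment` (per-channel integer vectors mapping each localization
#' row to its cluster id, 0 for background).
#' @examples
#' sim <- simulate_localizations(sim_config(seed = 7))
#' head(sim$ch1)
#' table(sim$truth$clusters$channel)
#' @export
simulate_localizations <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created by sim_config()")
  }
  with_seed(config$seed, {
    area_um2 <- config$roi_width_nm * config$roi_height_nm / 1e6

    draw_centers <- function(density) {
      n <- rpois(1L, density * area_um2)
      cbind(
        x = runif(n, 0, config$roi_width_nm),
        y = runif(n, 0, config$roi_height_nm)
      )
    }

    cen1 <- draw_centers(config$density_ch1)
    cen2 <- draw_centers(config$density_ch2)
    n1 <- nrow(cen1)
    n2 <- nrow(cen2)
    area1 <- rexp(n1, rate = 1 / config$mean_area_ch1_nm2)
    area2 <- rexp(n2, rate = 1 / config$mean_area_ch2_nm2)

    # Pair a coloc_fraction subset of ch2 clusters with distinct ch1
    # partners: the partner's center is copied (plus optional offset).
    partner1 <- rep(NA_integer_, n1)
    partner2 <- rep(NA_integer_, n2)
    n_pair <- min(round(config$coloc_fraction * n2), n1, n2)
    if (n_pair > 0) {
      i2 <- sample.int(n2, n_pair)
      i1 <- sample.int(n1, n_pair)
      cen2[i2, ] <- cen1[i1, , drop = FALSE]
      if (config$coloc_offset_nm > 0) {
        cen2[i2, ] <- cen2[i2, , drop = FALSE] +
          matrix(rnorm(2 * n_pair, sd = config$coloc_offset_nm), ncol = 2)
      }
      partner2[i2] <- i1
      partner1[i1] <- i2
    }

    scatter_channel <- function(centers, areas) {
      n_clu <- nrow(centers)
      n_locs <- if (n_clu) rpois(n_clu, config$locs_per_cluster) else integer(0)
      total <- sum(n_locs)
      cluster_id <- rep(seq_len(n_clu), n_locs)
      if (total > 0) {
        radius <- sqrt(areas / pi)[cluster_id]
        rr <- radius * sqrt(runif(total))
        th <- runif(total, 0, 2 * pi)
        x <- centers[cluster_id, 1] + rr * cos(th) +
          rnorm(total, sd = config$precision_sd_nm)
        y <- centers[cluster_id, 2] + rr * sin(th) +
          rnorm(total, sd = config$precision_sd_nm)
      } else {
        x <- y <- numeric(0)
      }
      n_bg <- rpois(1L, config$background_density * area_um2)
      x <- c(x, runif(n_bg, 0, config$roi_width_nm))
      y <- c(y, runif(n_bg, 0, config$roi_height_nm))
      assignment <- c(cluster_id, rep(0L, n_bg))
      m <- length(x)
      tab <- data.frame(
        frame = sample.int(config$n_frames, m, replace = TRUE) - 1L,
        x_nm = x, y_nm = y,
        photons = rpois(m, config$mean_photons),
        sigma_nm = rep(config$psf_sd_nm, m),
        background = rep(2, m),
        precision_nm = rep(config$precision_sd_nm, m)
      )
      list(table = tab, assignment = assignment, n_locs = n_locs)
    }

    ch1 <- scatter_channel(cen1, area1)
    ch2 <- scatter_channel(cen2, area2)

    clusters <- rbind(
      if (n1) data.frame(
        channel = "ch1", id = seq_len(n1),
        x_nm = cen1[, 1], y_nm = cen1[, 2], area_nm2 = area1,
        n_locs = ch1$n_locs, partner_id = partner1
      ),
      if (n2) data.frame(
        channel = "ch2", id = seq_len(n2),
        x_nm = cen2[, 1], y_nm = cen2[, 2], area_nm2 = area2,
        n_locs = ch2$n_locs, partner_id = partner2
      )
    )
    if (is.null(clusters)) {
      clusters <- data.frame(
        channel = character(0), id = integer(0), x_nm = numeric(0),
        y_nm = numeric(0), area_nm2 = numeric(0), n_locs = integer(0),
        partner_id = integer(0)
      )
    }

    truth <- structure(
      list(
        clusters = clusters,
        assignment = list(ch1 = ch1$assignment, ch2 = ch2$assignment),
        roi_nm = c(width = config$roi_width_nm,
                   height = config$roi_height_nm)
      ),
      class = "ground_truth"
    )

    structure(
      list(ch1 = ch1$table, ch2 = ch2$table, truth = truth,
           config = config),
      class = "sim_localizations"
    )
  })
}

#' @export
print.sim_localizations <- function(x, ...) {
  cl <- x$truth$clusters
  cat("Simulated two-channel SMLM data\n")
  cat(sprintf("  ROI: %.1f x %.1f um\n",
              x$config$roi_width_nm / 1000, x$config$roi_height_nm / 1000))
  for (ch in c("ch1", "ch2")) {
    cat(sprintf("  %s: %d clusters, %d localizations\n",
                ch, sum(cl$channel == ch), nrow(x[[ch]])))
  }
  cat(sprintf("  colocalized pairs: %d\n",
              sum(!is.na(cl$partner_id) & cl$channel == "ch2")))
  invisible(x)
}
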