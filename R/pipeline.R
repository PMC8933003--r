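#' Run the simulate-cluster-colocalize pipeline as one reproducible unit
#'
#' Executes the enabled stages in dependency order -- `simulate`
#' (two-channel localization tables with ground truth), `cluster`
#' (segmentation of both channels) and `coloc` (nearest-neighbor,
#' overlap, and Costes-style randomization) -- and assembles a report
#' of the headline statistics. The single global seed is expanded into
#' fixed per-stage seeds so any stage can be rerun independently yet
#' reproducibly; reruns with the same config and seed are bit-identical.
#' When `out_dir` is given, every intermediate artifact (localization
#' CSVs, ground-truth JSON, cluster-map JSONs, report JSON) is written
#' there.
#'
#' @param config Nested list (or path to a YAML file) with optional
#'   blocks `sim` (arguments for [sim_config()]), `cluster` (arguments
#'   for [segment_clusters()]) and `coloc` (`n_iter`, `min_shared_px`),
#'   plus `stages` (default all three) and `seed`.
#' @param out_dir Optional output directory for artifacts.
#' @return List of class `run_report` with per-stage summaries and the
#'   stage outputs (`sim`, `maps`, `coloc`).
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(seed = 3,
#'                          sim = list(roi_width_nm = 5000,
#'                                     roi_height_nm = 5000),
#'                          coloc = list(n_iter = 200)))
#' rep$summary
#' }
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "cluster", "coloc")
  seed <- as.integer(config$seed %||% 1L)
  # fixed counter scheme: stage k gets seed + k * 100003 (kept well
  # below .Machine$integer.max for small user seeds)
  stage_seed <- function(k) seed + k * 100003L
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list(seed = seed, stages = stages, summary = list())

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sim <- NULL
  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", {
      sim_args <- config$sim %||% list()
      sim_args$seed <- stage_seed(1L)
      simulate_localizations(do.call(sim_config, sim_args))
    })
    report$sim <- sim
    cl <- sim$truth$clusters
    report$summary$simulate <- list(
      n_clusters_ch1 = sum(cl$channel == "ch1"),
      n_clusters_ch2 = sum(cl$channel == "ch2"),
      n_coloc_pairs = sum(!is.na(cl$partner_id) & cl$channel == "ch2"),
      n_locs_ch1 = nrow(sim$ch1), n_locs_ch2 = nrow(sim$ch2)
    )
    if (!is.null(out_dir)) {
      write_localizations(sim$ch1, file.path(out_dir, "locs_ch1.csv"))
      write_localizations(sim$ch2, file.path(out_dir, "locs_ch2.csv"))
      write_ground_truth(sim$truth,
                         file.path(out_dir, "ground_truth.json"))
    }
  }

  maps <- NULL
  if ("cluster" %in% stages) {
    if (is.null(sim)) stop("stage 'cluster' requires stage 'simulate'")
    maps <- run_stage("cluster", {
      roi <- c(0, sim$config$roi_width_nm, 0, sim$config$roi_height_nm)
      cl_args <- config$cluster %||% list()
      lapply(list(ch1 = sim$ch1, ch2 = sim$ch2), function(tab) {
        do.call(segment_clusters, c(list(table = tab, roi = roi), cl_args))
      })
    })
    report$maps <- maps
    report$summary$cluster <- lapply(maps, function(m) {
      list(n_clusters = nrow(m$clusters),
           density_per_um2 = cluster_density(m),
           area_fit = if (nrow(m$clusters) >= 2) {
             unclass(fit_exponential_area(m))
           })
    })
    if (!is.null(out_dir)) {
      write_cluster_map(maps$ch1, file.path(out_dir, "clusters_ch1.json"))
      write_cluster_map(maps$ch2, file.path(out_dir, "clusters_ch2.json"))
    }
  }

  if ("coloc" %in% stages) {
    if (is.null(maps)) stop("stage 'coloc' requires stage 'cluster'")
    coloc <- run_stage("coloc", {
      co_args <- config$coloc %||% list()
      nn <- nearest_neighbor_distances(maps$ch1, maps$ch2)
      ov <- overlap_fraction(maps$ch1, maps$ch2,
                             min_shared_px = co_args$min_shared_px %||% 1)
      rand <- costes_randomize(
        maps$ch1, maps$ch2,
        n_iter = co_args$n_iter %||% 1000,
        seed = stage_seed(3L),
        min_shared_px = co_args$min_shared_px %||% 1
      )
      list(nn = nn, overlap = ov, randomization = rand)
    })
    report$coloc <- coloc
    report$summary$coloc <- list(
      nn_mean_nm = coloc$nn$mean_nm,
      overlap_a_pct = 100 * coloc$overlap$fraction_a,
      overlap_b_pct = 100 * coloc$overlap$fraction_b,
      null_mean_pct = 100 * coloc$randomization$null_mean,
      p_value = coloc$randomization$p_value
    )
  }

  skipped <- setdiff(c("simulate", "cluster", "coloc"), stages)
  if (length(skipped)) report$summary$skipped_stages <- skipped
  if (!is.null(out_dir)) {
    jsonlite::write_json(report$summary,
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(report, class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d)\n", x$seed))
  s <- x$summary
  if (!is.null(s$simulate)) {
    cat(sprintf("  simulate: %d + %d clusters, %d colocalized pairs\n",
                s$simulate$n_clusters_ch1, s$simulate$n_clusters_ch2,
                s$simulate$n_coloc_pairs))
  }
  if (!is.null(s$cluster)) {
    for (ch in names(s$cluster)) {
      cat(sprintf("  cluster %s: %d clusters, %.2f /um^2\n", ch,
                  s$cluster[[ch]]$n_clusters,
                  s$cluster[[ch]]$density_per_um2))
    }
  }
  if (!is.null(s$coloc)) {
    cat(sprintf(
      "  coloc: NN mean %.1f nm; overlap %.1f%% vs null %.2f%% (p = %.4g)\n",
      s$coloc$nn_mean_nm, s$coloc$overlap_a_pct, s$coloc$null_mean_pct,
      s$coloc$p_value))
  }
  if (!is.null(s$skipped_stages)) {
    cat("  skipped stages:", paste(s$skipped_stages, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ground-truth recovery benchmark over a parameter grid
#'
#' For every grid row and seed, simulates a data set, runs segmentation
#' and colocalization, and tabulates ground truth against the
#' estimates for cluster density, exponential area mean, colocalized
#' fraction and nearest-neighbor mean distance. Grid columns must be
#' [sim_config()] argument names; unspecified parameters keep their
#' defaults.
#'
#' @param grid data.frame of simulator parameter combinations (may have
#'   zero columns for the default configuration).
#' @param seeds Integer vector of simulation seeds.
#' @param cluster_args List of arguments for [segment_clusters()].
#' @param out_csv Optional path to write the table to.
#' @return data.frame with one row per grid point x seed holding true
#'   and estimated values plus relative biases.
#' @export
benchmark_recovery <- function(grid = data.frame(seed_dummy = 1)[, 0],
                               seeds = 1L, cluster_args = list(),
                               out_csv = NULL) {
  grid <- as.data.frame(grid)
  n_pts <- max(1L, nrow(grid))
  rows <- list()
  for (g in seq_len(n_pts)) {
    base_args <- if (nrow(grid)) as.list(grid[g, , drop = FALSE]) else list()
    for (s in seeds) {
      args <- base_args
      args$seed <- as.integer(s)
      cfg <- do.call(sim_config, args)
      sim <- simulate_localizations(cfg)
      roi <- c(0, cfg$roi_width_nm, 0, cfg$roi_height_nm)
      m1 <- do.call(segment_clusters,
                    c(list(table = sim$ch1, roi = roi), cluster_args))
      m2 <- do.call(segment_clusters,
                    c(list(table = sim$ch2, roi = roi), cluster_args))
      cl <- sim$truth$clusters
      area_um2 <- cfg$roi_width_nm * cfg$roi_height_nm / 1e6
      true_density1 <- sum(cl$channel == "ch1") / area_um2
      true_area1 <- mean(cl$area_nm2[cl$channel == "ch1"])
      n2 <- sum(cl$channel == "ch2")
      true_coloc <- if (sum(cl$channel == "ch1")) {
        sum(!is.na(cl$partner_id) & cl$channel == "ch1") /
          sum(cl$channel == "ch1")
      } else NA_real_
      # true NN mean over generated centroids
      a <- cl[cl$channel == "ch1", ]
      b <- cl[cl$channel == "ch2", ]
      true_nn <- if (nrow(a) && nrow(b)) {
        mean(vapply(seq_len(nrow(a)), function(i) {
          sqrt(min((a$x_nm[i] - b$x_nm)^2 + (a$y_nm[i] - b$y_nm)^2))
        }, numeric(1)))
      } else NA_real_
      est_density1 <- cluster_density(m1)
      est_area1 <- if (nrow(m1$clusters) >= 2) {
        fit_exponential_area(m1)$mean
      } else NA_real_
      est_coloc <- if (nrow(m1$clusters) && nrow(m2$clusters)) {
        overlap_fraction(m1, m2)$fraction_a
      } else NA_real_
      est_nn <- if (nrow(m1$clusters) && nrow(m2$clusters)) {
        nearest_neighbor_distances(m1, m2)$mean_nm
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        grid_point = g, seed = s,
        true_density = true_density1, est_density = est_density1,
        true_area_mean = true_area1, est_area_mean = est_area1,
        true_coloc = true_coloc, est_coloc = est_coloc,
        true_nn_mean = true_nn, est_nn_mean = est_nn
      )
    }
  }
  out <- do.call(rbind, rows)
  for (q in c("density", "area_mean", "coloc", "nn_mean")) {
    out[[paste0("bias_", q)]] <-
      (out[[paste0("est_", q)]] - out[[paste0("true_", q)]]) /
      out[[paste0("true_", q)]]
  }
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
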