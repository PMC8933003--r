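test_that("render_map conserves counts and handles edge cases", {
  expect_true(all(render_map(empty <- data.frame(
    frame = integer(0), x_nm = numeric(0), y_nm = numeric(0)))$img == 0))
  one <- data.frame(frame = 0L, x_nm = 55, y_nm = 73)
  expect_equal(sum(render_map(one, pixel_nm = 10, blur_nm = 0,
                              roi = c(0, 200, 0, 200))$img), 1)
  # blur conserves mass for interior structure
  tab <- blob_table(1000, 1000, n = 200, spread = 40)
  dm <- render_map(tab, pixel_nm = 10, blur_nm = 30,
                   roi = c(0, 2000, 0, 2000))
  expect_equal(sum(dm$img), sum(dm$raw), tolerance = 1e-6)
})

test_that("segmentation isolates well-separated blobs", {
  roi <- c(0, 5000, 0, 5000)
  one <- segment_clusters(blob_table(2500, 2500, n = 50, spread = 20),
                          roi = roi)
  expect_equal(nrow(one$clusters), 1)
  expect_lt(sqrt((one$clusters$x_nm - 2500)^2 +
                   (one$clusters$y_nm - 2500)^2), 15)
  two <- segment_clusters(rbind(
    blob_table(1000, 1000, n = 50, seed = 1),
    blob_table(3000, 3000, n = 50, seed = 2)), roi = roi)
  expect_equal(nrow(two$clusters), 2)
  empty <- segment_clusters(blob_table(1, 1, n = 0), roi = roi)
  expect_equal(nrow(empty$clusters), 0)
})

test_that("segmentation count matches ground truth on sparse input", {
  hits <- vapply(1:6, function(s) {
    sim <- simulate_localizations(sim_config(
      roi_width_nm = 5000, roi_height_nm = 5000, density_ch1 = 1,
      density_ch2 = 0, coloc_fraction = 0, seed = s))
    m <- segment_clusters(sim$ch1, roi = c(0, 5000, 0, 5000))
    c(est = nrow(m$clusters),
      true = sum(sim$truth$clusters$channel == "ch1"))
  }, numeric(2))
  # pooled over seeds: within 3 * sqrt(total) of the realized count
  expect_lt(abs(sum(hits["est", ]) - sum(hits["true", ])),
            3 * sqrt(sum(hits["true", ])))
})

test_that("cluster density is count over ROI area", {
  empty <- segment_clusters(blob_table(1, 1, n = 0),
                            roi = c(0, 5000, 0, 5000))
  expect_equal(cluster_density(empty), 0)
  set.seed(1)
  m <- cluster_map_from_disks(
    cbind(runif(50, 0, 5000), runif(50, 0, 5000)),
    rep(2000, 50), roi = c(0, 5000, 0, 5000))
  expect_equal(cluster_density(m), 50 / 25)
})

test_that("segmentation is translation-equivariant", {
  tab <- rbind(blob_table(800, 900, n = 40, seed = 1),
               blob_table(2600, 1700, n = 40, seed = 2))
  roi <- c(0, 4000, 0, 4000)
  m0 <- segment_clusters(tab, roi = roi)
  shifted <- tab
  shifted$x_nm <- tab$x_nm + 500
  shifted$y_nm <- tab$y_nm + 300
  m1 <- segment_clusters(shifted, roi = roi)
  ord0 <- order(m0$clusters$x_nm); ord1 <- order(m1$clusters$x_nm)
  expect_equal(m1$clusters$x_nm[ord1], m0$clusters$x_nm[ord0] + 500,
               tolerance = 1e-6)
  expect_equal(m1$clusters$y_nm[ord1], m0$clusters$y_nm[ord0] + 300,
               tolerance = 1e-6)
})

test_that("member localization counts are conserved", {
  sim <- small_sim(seed = 5)
  # ROI covering every localization (jitter can leave the nominal ROI)
  roi <- c(min(sim$ch1$x_nm) - 10, max(sim$ch1$x_nm) + 10,
           min(sim$ch1$y_nm) - 10, max(sim$ch1$y_nm) + 10)
  m <- segment_clusters(sim$ch1, roi = roi, min_locs = 1)
  expect_equal(sum(m$clusters$n_locs), nrow(sim$ch1))
  m3 <- segment_clusters(sim$ch1, roi = roi, min_locs = 3)
  expect_lte(sum(m3$clusters$n_locs), nrow(sim$ch1))
})

test_that("footprints stay disjoint within a map", {
  sim <- small_sim(seed = 6)
  m <- segment_clusters(sim$ch1, roi = c(0, 5000, 0, 5000))
  all_px <- unlist(m$footprints)
  expect_equal(anyDuplicated(all_px), 0)
  expect_equal(m$clusters$area_nm2,
               vapply(m$footprints, length, integer(1)) * m$pixel_nm^2)
})

test_that("exponential area fit is the ML mean with a sane CI", {
  fit <- fit_exponential_area(c(1000, 3000))
  expect_equal(fit$mean, 2000)
  expect_true(fit$ci[1] < fit$mean && fit$mean < fit$ci[2])
  # parameter recovery at the reported cluster-size scale
  set.seed(42)
  areas <- rexp(5000, rate = 1 / 3702.5)
  fit2 <- fit_exponential_area(areas)
  expect_true(fit2$ci[1] <= 3702.5 && 3702.5 <= fit2$ci[2])
  expect_lt(fit2$ks_statistic, 0.05)
  # degenerate (constant) data are flagged by a large KS statistic
  fit3 <- fit_exponential_area(rep(2000, 100))
  expect_gt(fit3$ks_statistic, 0.3)
  expect_error(fit_exponential_area(c(1000)), "at least 2")
})
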