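test_that("background subtraction clips at zero and zeroes offsets", {
  set <- fret_image_set(matrix(100, 4, 4), matrix(50, 4, 4),
                        matrix(80, 4, 4), a = 0.2, d = 0.5,
                        offsets = c(0, 0, 0))
  expect_equal(subtract_background(set)$i_dd, set$i_dd)
  set2 <- fret_image_set(matrix(100, 4, 4), matrix(50, 4, 4),
                         matrix(80, 4, 4), offsets = c(100, 200, 30))
  sub <- subtract_background(set2)
  expect_true(all(sub$i_dd == 0))
  expect_true(all(sub$i_aa == 0))  # offset above intensity: clipped
  expect_gt(attr(sub, "clipped"), 0)
  expect_true(all(sub$offsets == 0))
})

test_that("bleed-through slopes are recovered from controls", {
  cfg_d <- fret_sim_config(efficiency = 0, donor = matrix(runif(256, 50, 200), 16),
                           acceptor = matrix(0, 16, 16), dim = c(16, 16),
                           a = 0.25, d = 0.6, noise_sd = 0, seed = 1)
  cfg_a <- fret_sim_config(efficiency = 0, donor = matrix(0, 16, 16),
                           acceptor = matrix(runif(256, 50, 200), 16),
                           dim = c(16, 16), a = 0.25, d = 0.6,
                           noise_sd = 0, seed = 2)
  co <- estimate_bleedthrough(simulate_fret_images(cfg_d),
                              simulate_fret_images(cfg_a))
  expect_equal(unname(co["d"]), 0.6, tolerance = 1e-8)
  expect_equal(unname(co["a"]), 0.25, tolerance = 1e-8)
  # 1% noise: slopes still within 5%
  cfg_an <- fret_sim_config(efficiency = 0, donor = matrix(0, 16, 16),
                            acceptor = matrix(runif(256, 50, 200), 16),
                            dim = c(16, 16), a = 0.25, d = 0.6,
                            noise_sd = 1, seed = 3)
  co_n <- estimate_bleedthrough(simulate_fret_images(cfg_d),
                                simulate_fret_images(cfg_an))
  expect_lt(abs(co_n[["a"]] / 0.25 - 1), 0.05)
  # degenerate constant control rejected
  flat <- fret_image_set(matrix(1, 4, 4), matrix(1, 4, 4),
                         matrix(1, 4, 4))
  expect_error(estimate_bleedthrough(flat, flat), "degenerate")
})

test_that("N-FRET is zero under pure bleed-through and scale-invariant", {
  set.seed(4)
  dd <- matrix(runif(64, 50, 150), 8, 8)
  aa <- matrix(runif(64, 50, 150), 8, 8)
  da <- 0.6 * dd + 0.25 * aa
  set <- fret_image_set(dd, aa, da, a = 0.25, d = 0.6)
  nf <- nfret_map(set)
  expect_lt(max(abs(nf$nfret[nf$valid])), 1e-9)
  # scaling all channels leaves N-FRET unchanged
  da2 <- da + 20 * sqrt(dd * aa) / 100  # inject 20% N-FRET
  s1 <- nfret_map(fret_image_set(dd, aa, da2, a = 0.25, d = 0.6))
  s2 <- nfret_map(fret_image_set(3 * dd, 3 * aa, 3 * da2,
                                 a = 0.25, d = 0.6))
  expect_equal(s2$roi_mean, s1$roi_mean, tolerance = 1e-12)
  expect_equal(s1$roi_mean, 20, tolerance = 1e-9)
})

test_that("zero-efficiency synthetic sets give null N-FRET", {
  cfg <- fret_sim_config(efficiency = 0, donor = 120, acceptor = 90,
                         dim = c(32, 32), a = 0.25, d = 0.6,
                         noise_sd = 0, seed = 5)
  nf <- nfret_map(simulate_fret_images(cfg))
  expect_lt(abs(nf$roi_mean), 1e-9)
})

test_that("N-FRET increases strictly with true efficiency", {
  means <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.4), function(e) {
    cfg <- fret_sim_config(efficiency = e, donor = 120, acceptor = 90,
                           dim = c(32, 32), a = 0.25, d = 0.6,
                           noise_sd = 0.5, seed = 6)
    nfret_map(simulate_fret_images(cfg))$roi_mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("masked ROI mean equals the plain mean over the mask", {
  cfg <- fret_sim_config(efficiency = 0.2, donor = 100, acceptor = 100,
                         dim = c(16, 16), noise_sd = 1, seed = 7)
  set <- simulate_fret_images(cfg)
  mask <- matrix(FALSE, 16, 16); mask[4:10, 6:12] <- TRUE
  nf <- nfret_map(set, mask = mask)
  expect_equal(nf$roi_mean, mean(nf$nfret[mask & nf$valid]))
})

test_that("a set with no valid pixels is flagged", {
  set <- fret_image_set(matrix(0, 4, 4), matrix(0, 4, 4),
                        matrix(0, 4, 4))
  expect_warning(nf <- nfret_map(set), "no valid pixels")
  expect_true(is.na(nf$roi_mean))
})
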