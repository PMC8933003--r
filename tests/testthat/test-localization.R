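test_that("thompson_precision matches its closed forms and scaling laws", {
  # q negligible, b = 0: sigma -> s / sqrt(N)
  expect_equal(thompson_precision(100, 1e-6, 100, 0), 10, tolerance = 1e-9)
  # independent scalar evaluation of the printed two-term expression
  s <- 150; q <- 100; n <- 400; b <- 1
  term_shot <- (s * s + q * q / 12) / n
  term_bg <- (8 * pi * s * s * s * s * b * b) / (q * q * n * n)
  expect_equal(thompson_precision(s, q, n, b), sqrt(term_shot + term_bg))
  # quadrupling N with b = 0 halves sigma
  expect_equal(thompson_precision(120, 100, 4 * 250, 0),
               thompson_precision(120, 100, 250, 0) / 2)
  # strictly decreasing in N, increasing in s and b
  ns <- c(100, 200, 500, 1000, 5000)
  expect_true(all(diff(thompson_precision(130, 100, ns, 2)) < 0))
  ss <- c(80, 100, 130, 160, 200)
  expect_true(all(diff(thompson_precision(ss, 100, 500, 2)) > 0))
  bs <- c(0, 1, 2, 4, 8)
  expect_true(all(diff(thompson_precision(130, 100, 500, bs)) > 0))
  expect_error(thompson_precision(-1, 100, 500), ">")
  expect_error(thompson_precision(130, 100, 500, -1), ">=")
})

test_that("fitting an exact noiseless emitter recovers its position", {
  stk <- noiseless_stack(x_nm = 743, y_nm = 691, s_nm = 130, q_nm = 100)
  loc <- fit_localizations(stk, detect_threshold = 10)
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$x_nm - 743), 1e-3 * 100)
  expect_lt(abs(loc$y_nm - 691), 1e-3 * 100)
  expect_equal(loc$sigma_nm, 130, tolerance = 0.01)
})

test_that("an all-zero stack yields an empty localization table", {
  stk <- simulate_frames(frame_sim_config(
    cbind(500, 500), fov_nm = c(1000, 1000), n_photons = 0,
    b_photons = 0, n_frames = 3, seed = 1))
  loc <- fit_localizations(stk)
  expect_equal(nrow(loc), 0)
})

test_that("empirical fit scatter is consistent with the precision formula", {
  s <- 130; q <- 100; n_ph <- 500; b <- 2
  stk <- simulate_frames(frame_sim_config(
    cbind(1200, 1200), fov_nm = c(2400, 2400), s_nm = s, q_nm = q,
    n_photons = n_ph, b_photons = b, n_frames = 150, seed = 21))
  loc <- fit_localizations(stk, detect_threshold = 8, psf_sd_nm = s)
  expect_gt(nrow(loc), 120)
  emp <- sqrt((var(loc$x_nm) + var(loc$y_nm)) / 2)
  expect_lt(abs(emp / thompson_precision(s, q, n_ph, b) - 1), 0.15)
})

test_that("early-frame exclusion filters by frame index", {
  tab <- blob_table(500, 500, n = 100)
  tab$frame <- 0:99
  expect_identical(exclude_early_frames(tab, 0), tab)
  kept <- exclude_early_frames(tab, 50)
  expect_equal(kept$frame, 50:99)
  expect_equal(nrow(exclude_early_frames(tab, 100)), 0)
})

test_that("drift correction recovers injected linear drift", {
  sim <- simulate_localizations(sim_config(seed = 11))
  tab <- sim$ch1
  rate_x <- 0.02; rate_y <- -0.01  # nm per frame
  tab$x_nm <- tab$x_nm + tab$frame * rate_x
  tab$y_nm <- tab$y_nm + tab$frame * rate_y
  dc <- drift_correct(tab, time_bin = 2000)
  end <- dc$drift[nrow(dc$drift), ]
  true_x <- max(tab$frame) * rate_x
  true_y <- max(tab$frame) * rate_y
  expect_lt(abs(end$dx_nm / true_x - 1), 0.1)
  expect_lt(abs(end$dy_nm / true_y - 1), 0.1)
})

test_that("drift correction is near-null without drift and idempotent", {
  sim <- simulate_localizations(sim_config(seed = 12))
  dc1 <- drift_correct(sim$ch1, time_bin = 2000, render_px_nm = 50)
  expect_lt(max(abs(c(dc1$drift$dx_nm, dc1$drift$dy_nm))), 50)
  # a second pass on corrected data estimates sub-pixel residual drift
  dc2 <- drift_correct(dc1$table, time_bin = 2000, render_px_nm = 50)
  expect_lt(max(abs(c(dc2$drift$dx_nm, dc2$drift$dy_nm))), 50)
})

test_that("drift correction rejects single-bin input", {
  tab <- blob_table(500, 500, n = 200)
  tab$frame <- rep(0:99, 2)
  expect_error(drift_correct(tab, time_bin = 1000), "2 time bins")
})
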