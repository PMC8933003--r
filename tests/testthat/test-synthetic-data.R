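test_that("zero densities and zero background give empty output", {
  sim <- simulate_localizations(sim_config(
    density_ch1 = 0, density_ch2 = 0, background_density = 0, seed = 1))
  expect_equal(nrow(sim$ch1), 0)
  expect_equal(nrow(sim$ch2), 0)
  expect_equal(nrow(sim$truth$clusters), 0)
})

test_that("coloc_fraction = 1 pairs every channel-2 cluster", {
  sim <- simulate_localizations(sim_config(
    roi_width_nm = 5000, roi_height_nm = 5000,
    coloc_fraction = 1, background_density = 0, seed = 2))
  cl <- sim$truth$clusters
  ch2 <- cl[cl$channel == "ch2", ]
  ch1 <- cl[cl$channel == "ch1", ]
  n_expected <- min(nrow(ch1), nrow(ch2))
  expect_equal(sum(!is.na(ch2$partner_id)), n_expected)
  # pairing is symmetric and cross-channel: partner centers coincide
  paired <- ch2[!is.na(ch2$partner_id), ]
  expect_equal(paired$x_nm, ch1$x_nm[paired$partner_id])
  expect_equal(ch1$partner_id[paired$partner_id], paired$id)
})

test_that("realized cluster counts follow the Poisson intensity", {
  counts <- vapply(1:100, function(s) {
    sim <- simulate_localizations(sim_config(
      locs_per_cluster = 1, coloc_fraction = 0, seed = s))
    sum(sim$truth$clusters$channel == "ch1")
  }, numeric(1))
  # mean of 100 Poisson(200) draws: se = sqrt(200/100)
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200 / 100))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(roi_width_nm = -1), "roi_width_nm")
  expect_error(sim_config(coloc_fraction = 1.5), "coloc_fraction")
  expect_error(frame_sim_config(cbind(900, 100), fov_nm = c(500, 500)),
               "inside the field")
  expect_error(trace_sim_config(flow_on_s = 100, flow_off_s = 50),
               "flow_on_s")
})

test_that("same seed and config reproduce identical outputs", {
  cfg <- sim_config(roi_width_nm = 3000, roi_height_nm = 3000, seed = 9)
  expect_identical(simulate_localizations(cfg),
                   simulate_localizations(cfg))
  fcfg <- frame_sim_config(cbind(500, 500), fov_nm = c(1000, 1000),
                           n_frames = 5, b_photons = 1, seed = 4)
  expect_identical(simulate_frames(fcfg), simulate_frames(fcfg))
  tcfg <- trace_sim_config(noise_sd_pa_pf = 0.1, seed = 5)
  expect_identical(simulate_current_trace(tcfg),
                   simulate_current_trace(tcfg))
})

test_that("frame simulator obeys its photon bookkeeping", {
  # no photons, no background -> all-zero stack
  stk0 <- simulate_frames(frame_sim_config(
    cbind(500, 500), fov_nm = c(1000, 1000), n_photons = 0,
    b_photons = 0, n_frames = 4, seed = 1))
  expect_true(all(stk0$counts == 0))
  # one always-on emitter, b = 0: per-frame sums are Poisson with mean N
  stk <- simulate_frames(frame_sim_config(
    cbind(1000, 1000), fov_nm = c(2000, 2000), n_photons = 300,
    b_photons = 0, n_frames = 300, duty_cycle = 1, seed = 2))
  sums <- apply(stk$counts, 3, sum)
  expect_lt(abs(mean(sums) - 300), 3 * sqrt(300 / 300))
  expect_lt(abs(var(sums) / mean(sums) - 1), 0.35)
  # doubling the pixel size halves the grid for a fixed field
  stq <- simulate_frames(frame_sim_config(
    cbind(500, 500), fov_nm = c(1000, 1000), q_nm = 200, n_frames = 1,
    seed = 3))
  expect_equal(dim(stq$counts)[1:2], dim(stk0$counts)[1:2] / 2)
})

test_that("FRET simulator reduces to pure bleed-through at efficiency 0", {
  cfg <- fret_sim_config(efficiency = 0, donor = 80, acceptor = 120,
                         dim = c(16, 16), a = 0.25, d = 0.6,
                         noise_sd = 0, offsets = c(5, 7, 9), seed = 1)
  set <- simulate_fret_images(cfg)
  expect_equal(set$i_da,
               0.25 * (set$i_aa - 7) + 0.6 * (set$i_dd - 5) + 9)
  # zero abundance: channels equal their offsets
  cfg0 <- fret_sim_config(efficiency = 0.3, donor = 0, acceptor = 0,
                          dim = c(8, 8), offsets = c(2, 3, 4), seed = 1)
  set0 <- simulate_fret_images(cfg0)
  expect_true(all(set0$i_dd == 2) && all(set0$i_aa == 3) &&
                all(set0$i_da == 4))
})

test_that("trace simulator realizes the biphasic flow response exactly", {
  flat <- simulate_current_trace(trace_sim_config(
    transient_amp_pa_pf = 0, sustained_shift_pa_pf = 0,
    noise_sd_pa_pf = 0, seed = 1))
  expect_true(all(abs(current_density(flat) - (-5.5)) < 1e-12))
  tr <- simulate_current_trace(trace_sim_config(noise_sd_pa_pf = 0,
                                                seed = 1))
  dens <- current_density(tr)
  # the flow-onset minimum sits at baseline + transient amplitude
  expect_equal(min(dens) - (-5.5), -1.3, tolerance = 1e-12)
  # a late in-flow window sits at baseline + sustained shift
  late <- dens[tr$time_s >= 140 & tr$time_s < 150]
  expect_equal(mean(late) - (-5.5), 4.53, tolerance = 1e-6)
})

test_that("ground truth round-trips through JSON serialization", {
  sim <- small_sim(seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$clusters, sim$truth$clusters)
  expect_equal(back$assignment$ch1, sim$truth$assignment$ch1)
  expect_equal(unname(back$roi_nm), unname(sim$truth$roi_nm))
})
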