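test_that("zero diffusion and zero noise give identically zero displacements", {
  spec <- simulation_spec(n_immobile = 3, n_mobile = 3, D_um2_s = 0,
                          loc_noise_nm = 0, n_frames = 20, seed = 11)
  truth <- simulate_trajectories(spec)
  trajs <- truth_to_trajectories(truth)
  slds <- unlist(sld_by_track(trajs))
  expect_true(all(slds == 0))
})

test_that("Brownian mean step matches the analytic Rayleigh mean", {
  # per-axis var 2*D*dt => step ~ Rayleigh, mean sqrt(pi*D*dt)
  D <- 0.01; fps <- 10
  spec <- simulation_spec(n_immobile = 0, n_mobile = 400, D_um2_s = D,
                          loc_noise_nm = 0, n_frames = 20, fps = fps,
                          image_size_px = 256, seed = 21)
  truth <- simulate_trajectories(spec)
  slds <- unlist(sld_by_track(truth_to_trajectories(truth)))
  analytic <- sqrt(pi * D * (1 / fps))
  expect_equal(mean(slds), analytic, tolerance = 0.02)
})

test_that("seeded generators are bit-reproducible", {
  spec <- simulation_spec(n_immobile = 2, n_mobile = 2, n_frames = 10,
                          image_size_px = 32, seed = 5)
  expect_identical(simulate_trajectories(spec), simulate_trajectories(spec))
  truth <- simulate_trajectories(spec)
  expect_identical(render_movie(truth, spec)$data, render_movie(truth, spec)$data)
  expect_identical(simulate_flicker_trace(spec, 100), simulate_flicker_trace(spec, 100))
  mspec <- mnr_spec(n_puncta = 5, n_blobs = 1, n_spurious = 2, n_frames = 5,
                    image_size_px = 96, lumen_radius_um = 2, outer_radius_um = 4,
                    seed = 9)
  expect_identical(simulate_mnr_scene(mspec)$movie$data,
                   simulate_mnr_scene(mspec)$movie$data)
})

test_that("flicker traces follow the two-state stationary statistics", {
  # k_open = 0: closed forever, intensity = dim baseline
  spec0 <- simulation_spec(k_open = 0, k_close = 2, dim_fraction = 0,
                           photons_per_punctum = 100, fps = 100, seed = 3)
  tr0 <- simulate_flicker_trace(spec0, 500)
  expect_true(all(tr0$n_open == 0))
  expect_true(all(tr0$photons == 0))
  # k_open = k_close: occupancy 0.5 within Monte-Carlo error
  spec1 <- simulation_spec(k_open = 3, k_close = 3, fps = 100, seed = 13)
  tr1 <- simulate_flicker_trace(spec1, 20000)
  expect_equal(mean(tr1$n_open), 0.5, tolerance = 0.05)
  # cluster of 3, all open, dim_fraction 0: exactly 3 x unitary brightness
  spec3 <- simulation_spec(k_open = 10, k_close = 0, cluster_size = 3,
                           dim_fraction = 0, photons_per_punctum = 100,
                           seed = 2)
  tr3 <- simulate_flicker_trace(spec3, 50)
  expect_true(all(tr3$photons[tr3$n_open == 3] == 300))
  expect_equal(tail(tr3$n_open, 1), 3)  # absorbing open state
})

test_that("rendering conserves the photon budget and the bleach law", {
  px <- 0.108
  spec <- simulation_spec(n_immobile = 1, n_mobile = 0, loc_noise_nm = 0,
                          photons_per_punctum = 2000, background_photons = 0,
                          black_level_cu = 50, n_frames = 1, image_size_px = 48,
                          shot_noise = FALSE, seed = 31)
  # zero puncta, zero background, no noise: uniform black level
  blank <- render_movie(empty <- simulate_trajectories(
    simulation_spec(n_immobile = 0, n_mobile = 0, n_frames = 2,
                    background_photons = 0, shot_noise = FALSE,
                    black_level_cu = 50, image_size_px = 16)),
    simulation_spec(n_immobile = 0, n_mobile = 0, n_frames = 2,
                    background_photons = 0, shot_noise = FALSE,
                    black_level_cu = 50, image_size_px = 16))
  expect_true(all(blank$data == 50))
  # photon budget recovered from pixel sums within 1%
  truth <- simulate_trajectories(spec)
  mov <- render_movie(truth, spec)
  photons <- (sum(get_frame(mov, 0)) - 48 * 48 * 50) * spec$gain_pe_per_cu
  expect_equal(photons, 2000, tolerance = 0.01)
  # amplitude ratio e:1 between frame 0 and the frame at t = tau
  tau <- 38.1
  spec_b <- simulation_spec(n_immobile = 1, n_mobile = 0, loc_noise_nm = 0,
                            photons_per_punctum = 2000, background_photons = 0,
                            black_level_cu = 0, bleach_tau_s = tau, fps = 10,
                            n_frames = 382, image_size_px = 48,
                            shot_noise = FALSE, quantize = FALSE, seed = 31)
  truth_b <- simulate_trajectories(spec_b)
  mov_b <- render_movie(truth_b, spec_b)
  s0 <- sum(get_frame(mov_b, 0))
  s1 <- sum(get_frame(mov_b, 381))  # t = 38.1 s
  expect_equal(s0 / s1, exp(1), tolerance = 1e-3)
})

test_that("un-enriched organoid puncta are uniform over the tissue annulus", {
  mspec <- mnr_spec(n_puncta = 1000, n_blobs = 0, n_spurious = 0, n_frames = 1,
                    lumen_radius_um = 4, outer_radius_um = 9,
                    lumen_enrichment = 0, image_size_px = 192, seed = 17)
  scene <- simulate_mnr_scene(mspec)
  tp <- scene$truth[scene$truth$type == "punctum", ]
  centre <- (192 - 1) / 2 * 0.108
  r <- sqrt((tp$x_um - centre)^2 + (tp$y_um - centre)^2)
  expect_true(all(r > 4 & r < 9))
  # fraction within 2 um of the lumen border vs the annulus area ratio,
  # within ~3.5 binomial SDs at n = 1000
  frac <- mean(r - 4 <= 2)
  area_frac <- (6^2 - 4^2) / (9^2 - 4^2)
  expect_lt(abs(frac - area_frac), 3.5 * sqrt(area_frac * (1 - area_frac) / 1000))
})

test_that("sub-Brownian tracks have depressed long-lag MSD", {
  spec <- simulation_spec(n_immobile = 0, n_mobile = 150, D_um2_s = 0.029,
                          anomalous_alpha = 0.6, loc_noise_nm = 0,
                          n_frames = 40, fps = 10, seed = 23)
  truth <- simulate_trajectories(spec)
  mm <- mean_msd(compute_msd(truth_to_trajectories(truth), 0.1, max_lag_s = 3))
  # MSD = 4 D t^alpha: ratio MSD(2 s)/MSD(0.2 s) = 10^alpha, well below 10
  ratio <- mm$msd_um2[mm$lag_s == 2] / mm$msd_um2[abs(mm$lag_s - 0.2) < 1e-9]
  expect_equal(ratio, 10^0.6, tolerance = 0.15)
  expect_lt(ratio, 7)
})
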