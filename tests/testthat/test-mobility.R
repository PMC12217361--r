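test_that("single lag displacements follow the track geometry", {
  static <- make_traj(rep(1, 5), rep(2, 5))
  expect_true(all(compute_sld(static) == 0))
  expect_equal(compute_sld(make_traj(c(0, 3), c(0, 4))), 5)
  # an interpolated midpoint yields two equal SLDs of half the full distance
  tr <- make_traj(c(0, 1, 2), c(0, 0.5, 1),
                  interpolated = c(FALSE, TRUE, FALSE))
  d_full <- sqrt(2^2 + 1^2)
  expect_equal(compute_sld(tr), rep(d_full / 2, 2))
  expect_length(compute_sld(make_traj(1, 1)), 0)
})

test_that("exponential CDF fits recover scales and separate model classes", {
  set.seed(42)
  lam <- 0.012
  one <- rexp(2000, rate = 1 / lam)
  f1 <- fit_sld_cdf(one, 1)
  f2 <- fit_sld_cdf(one, 2)
  expect_equal(f1$scales, lam, tolerance = 0.05)
  expect_lt(f1$rss / f2$rss, 1.5)    # exp2 not materially better
  # 50/50 mixture with a 10x scale split
  mix <- c(rexp(2000, 1 / lam), rexp(2000, 1 / (10 * lam)))
  g1 <- fit_sld_cdf(mix, 1)
  g2 <- fit_sld_cdf(mix, 2)
  expect_gte(g1$rss / g2$rss, 5)
  expect_equal(g2$weights, c(0.5, 0.5), tolerance = 0.1)
  expect_equal(g2$scales[1], lam, tolerance = 0.2)
  expect_equal(g2$scales[2], 10 * lam, tolerance = 0.2)
  expect_error(fit_sld_cdf(rep(0, 100)), "degenerate")
  expect_error(fit_sld_cdf(rexp(10)), "at least 50")
})

test_that("path lengths sum SLDs over the window and classify by the cutoff", {
  static <- make_traj(rep(1, 60), rep(1, 60))
  p <- path_lengths(static, window_s = 5, frame_interval_s = 0.1)
  expect_equal(p$path_um, 0)
  # square loop of four 1-um steps
  sq <- make_traj(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  psq <- path_lengths(sq, window_s = 5, frame_interval_s = 1)
  expect_equal(psq$path_um, 4)
  # too-short tracks are excluded, not an error
  short <- make_traj(c(0, 1), c(0, 0))
  expect_true(is.na(path_lengths(short, 5, 0.1)$path_um))
  # Brownian mean path ~ (n-1) * sqrt(pi * D * dt)
  D <- 0.029; dt <- 0.1
  spec <- simulation_spec(n_immobile = 0, n_mobile = 300, D_um2_s = D,
                          loc_noise_nm = 0, n_frames = 50, fps = 10, seed = 8)
  paths <- path_lengths(truth_to_trajectories(simulate_trajectories(spec)),
                        5, dt)
  expect_equal(mean(paths$path_um), 49 * sqrt(pi * D * dt), tolerance = 0.02)
  # classification boundary is strict
  expect_equal(classify_mobility(c(2, 3, 3.2)),
               c("immobile", "immobile", "mobile"))
})

test_that("the path-length mixture fit resolves two populations", {
  set.seed(15)
  paths <- c(rnorm(600, 1.5, 0.3), rnorm(400, 4.7, 0.6))
  fit <- fit_path_length_mixture(paths)
  expect_equal(fit$means[1], 1.5, tolerance = 0.1)
  expect_equal(fit$means[2], 4.7, tolerance = 0.1)
  expect_true(fit$means[1] < 3 && fit$means[2] > 3)
  expect_equal(fit$weights[1], 0.6, tolerance = 0.1)
  # a single population collapses to one effective component
  single <- rnorm(800, 1.2, 0.15)
  fs <- fit_path_length_mixture(single)
  expect_true(min(fs$weights) < 0.1 ||
                abs(diff(fs$means)) < 0.3)
  expect_error(fit_path_length_mixture(rep(2, 200)), "degenerate")
})

test_that("MSD equals the brute-force all-pairs oracle on toy tracks", {
  set.seed(9)
  for (n in c(5, 12)) {
    x <- cumsum(rnorm(n, sd = 0.1)); y <- cumsum(rnorm(n, sd = 0.1))
    got <- compute_msd(make_traj(x, y), frame_interval_s = 0.1, max_lag_s = 2)
    want <- brute_msd(x, y, 0.1, 2)
    expect_equal(got$lag_s, want$lag_s)
    expect_equal(got$msd_um2, want$msd_um2, tolerance = 1e-12)
  }
  # static noiseless track: MSD identically zero, D = 0
  st <- compute_msd(make_traj(rep(2, 30), rep(3, 30)), 0.1, 2)
  expect_true(all(st$msd_um2 == 0))
  expect_equal(fit_diffusion(mean_msd(st))$D_um2_s, 0)
  expect_error(fit_diffusion(mean_msd(st)[1:2, ]), "3 lag points")
})

test_that("localization error summarises radial deviation from track means", {
  same <- make_traj(rep(1, 10), rep(1, 10))
  expect_equal(localization_error(same)$mean_nm, 0)
  cross <- make_traj(c(1, -1, 0, 0), c(0, 0, 1, -1))
  expect_equal(localization_error(cross)$mean_nm, 1000)  # 1 um by symmetry
  # Gaussian noise: mean radial deviation s*sqrt(pi/2)*sqrt((n-1)/n)
  s <- 29; n <- 50
  set.seed(33)
  trs <- do.call(rbind, lapply(1:200, function(i)
    make_traj(rnorm(n, sd = s / 1000), rnorm(n, sd = s / 1000), track_id = i)))
  got <- localization_error(trs)$mean_nm
  expect_equal(got, s * sqrt(pi / 2) * sqrt((n - 1) / n), tolerance = 0.02)
})

test_that("bleach fitting recovers the time constant and flags flat traces", {
  t <- seq(0, 120, by = 0.1)
  fit <- bleach_time_constant(4000 * exp(-t / 38.1), t)
  expect_equal(fit$tau_s, 38.1, tolerance = 1e-4)
  expect_warning(flat <- bleach_time_constant(rep(5, 100), seq_len(100)),
                 "does not decay")
  expect_true(is.na(flat$tau_s))
})

test_that("signal-to-background uses black-level-subtracted 3x3 ROIs", {
  img <- matrix(100 + 20, 32, 32)       # black level 100, background 20 c.u.
  img[9:11, 9:11] <- 100 + 100           # punctum ROI adds 4 x background
  mov <- movie_stack(array(img, c(1, 32, 32)), 0.108, 0.1,
                     black_level_cu = 100)
  locs <- localization_table(frame = 0L, x_nm = 9 * 108, y_nm = 9 * 108,
                             sigma_nm = 189, intensity_photons = 100,
                             background_photons = 1)
  sb <- signal_to_background(mov, locs, background_roi = c(25, 25))
  expect_equal(sb$mean, 5)
  # signal equal to background gives ratio 1
  mov1 <- movie_stack(array(120, c(1, 32, 32)), 0.108, 0.1,
                      black_level_cu = 100)
  expect_equal(signal_to_background(mov1, locs, c(25, 25))$mean, 1)
  # background ROI overlapping a detection is an error
  expect_error(signal_to_background(mov, locs, c(10, 10)), "overlaps")
  # black level only: undefined ratio
  mov0 <- movie_stack(array(100, c(1, 32, 32)), 0.108, 0.1,
                      black_level_cu = 100)
  expect_error(signal_to_background(mov0, locs, c(25, 25)), "black level")
})
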