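test_that("calcium-mode filtering keeps the 261 c.u. boundary inclusively", {
  gain <- 0.229
  locs <- localization_table(frame = 0:2, x_nm = c(1, 2, 3) * 1000,
                             y_nm = rep(1000, 3), sigma_nm = rep(189, 3),
                             intensity_photons = c(260, 261, 262) * gain,
                             background_photons = rep(1, 3))
  kept <- filter_mnr_detections(locs, "calcium", pixel_size_um = 0.108,
                                gain_pe_per_cu = gain)
  expect_equal(round(kept$intensity_photons / gain), c(261, 262))
})

test_that("static-mode filtering removes short tracks and returns mean positions", {
  px_nm <- 108
  mk <- function(frames, x_px, y_px)
    localization_table(frame = frames, x_nm = x_px * px_nm, y_nm = y_px * px_nm,
                       sigma_nm = 189, intensity_photons = 100,
                       background_photons = 1)
  # a 3-frame contaminant track and a 5-frame punctum
  locs <- rbind(mk(0:2, c(5, 5.1, 5.2), rep(5, 3)),
                mk(0:4, c(30, 30.1, 30.2, 30.3, 30.4), rep(30, 5)))
  out <- filter_mnr_detections(locs, "static_label", pixel_size_um = 0.108)
  expect_equal(nrow(out), 1L)
  expect_equal(out$x_nm, mean(c(30, 30.1, 30.2, 30.3, 30.4)) * px_nm)
  expect_equal(out$n_frames, 5L)
})

test_that("the full organoid filter chain isolates true puncta from contaminants", {
  mspec <- mnr_spec(n_puncta = 10, n_blobs = 5, n_spurious = 8,
                    lumen_radius_um = 3, outer_radius_um = 12,
                    image_size_px = 256, n_frames = 12, seed = 101)
  scene <- simulate_mnr_scene(mspec)
  locs <- detect_and_localize(scene$movie, detection_params(fit_box_px = 11))
  found <- filter_mnr_detections(locs, "static_label", pixel_size_um = 0.108)
  expect_equal(nrow(found), 10L)
  # each retained mean position matches a distinct true punctum within 1 px
  tp <- scene$truth[scene$truth$type == "punctum", ]
  d <- outer(found$x_nm / 1000, tp$x_um, "-")^2 +
    outer(found$y_nm / 1000, tp$y_um, "-")^2
  nearest <- apply(sqrt(d), 1, which.min)
  expect_equal(sort(nearest), 1:10)
  expect_true(all(apply(sqrt(d), 1, min) < 0.108))
  # contaminant-only scene: the chain retains nothing
  kspec <- mnr_spec(n_puncta = 0, n_blobs = 5, n_spurious = 8,
                    lumen_radius_um = 3, outer_radius_um = 12,
                    image_size_px = 256, n_frames = 12, seed = 102)
  kscene <- simulate_mnr_scene(kspec)
  klocs <- detect_and_localize(kscene$movie, detection_params(fit_box_px = 11))
  expect_equal(nrow(filter_mnr_detections(klocs, "static_label", 0.108)), 0L)
})

test_that("mask distances use a ceil-rounded Euclidean distance transform", {
  mask <- matrix(FALSE, 40, 40); mask[20, 20] <- TRUE
  other <- matrix(FALSE, 40, 40); other[1, 1] <- TRUE
  px <- 0.108; px_nm <- px * 1000
  pos <- function(row, col)  # 0-based pixel -> nm position
    data.frame(x_nm = col * px_nm, y_nm = row * px_nm)
  # on the mask: distance zero
  d0 <- distances_to_masks(pos(19, 19), mask, other, px)
  expect_equal(d0$d_lumen_um, 0)
  # exactly 5.0 px away (3-4-5): ceil(5) = 5 px = 0.54 um
  d5 <- distances_to_masks(pos(19 + 3, 19 + 4), mask, other, px)
  expect_equal(d5$d_lumen_um, 5 * px)
  # sqrt(10) ~ 3.2 px away: rounded up to 4 px
  d32 <- distances_to_masks(pos(19 + 1, 19 + 3), mask, other, px)
  expect_equal(d32$d_lumen_um, 4 * px)
  expect_error(distances_to_masks(pos(19, 100), mask, other, px), "outside")
})

test_that("distance transform agrees with brute-force nearest-pixel search", {
  set.seed(55)
  for (rep in 1:3) {
    mask <- matrix(runif(30 * 30) < 0.03, 30, 30)
    if (!any(mask)) mask[15, 15] <- TRUE
    other <- matrix(FALSE, 30, 30); other[2, 2] <- TRUE
    rows <- sample(0:29, 25, replace = TRUE)
    cols <- sample(0:29, 25, replace = TRUE)
    got <- distances_to_masks(
      data.frame(x_nm = cols * 108, y_nm = rows * 108), mask, other, 0.108)
    want <- sapply(seq_along(rows), function(i)
      ceiling(brute_mask_distance_px(mask, rows[i] + 1, cols[i] + 1) - 1e-9) * 0.108)
    expect_equal(got$d_lumen_um, want, tolerance = 1e-12)
  }
})

test_that("the distance density scatter behaves like a product-kernel KDE", {
  # single cluster: maximum at the cluster coordinate
  set.seed(77)
  dl <- rnorm(40, 10, 0.1); do <- rnorm(40, 20, 0.1)
  ds <- density_scatter(dl, do)
  peak <- which(ds$z == max(ds$z), arr.ind = TRUE)
  expect_equal(ds$x[peak[1]], 10, tolerance = 0.05)
  expect_equal(ds$y[peak[2]], 20, tolerance = 0.05)
  # two equal clusters: equal peak densities within 1%
  dl2 <- c(rep(5, 30), rep(45, 30)); do2 <- c(rep(5, 30), rep(45, 30))
  ds2 <- density_scatter(dl2, do2)
  p1 <- ds2$point_density[1]; p2 <- ds2$point_density[31]
  expect_equal(p1 / p2, 1, tolerance = 0.01)
  # uniform grid: near-flat interior density (CV < 10%)
  g <- expand.grid(x = seq(0, 40, by = 2), y = seq(0, 40, by = 2))
  ds3 <- density_scatter(g$x, g$y)
  interior <- g$x >= 12 & g$x <= 28 & g$y >= 12 & g$y <= 28
  pd <- ds3$point_density[interior]
  expect_lt(sd(pd) / mean(pd), 0.10)
  expect_error(density_scatter(1, 1), "at least 2")
})

test_that("distance summaries give area-one histograms, ECDF and near fractions", {
  all0 <- distance_summary(rep(0, 10))
  expect_equal(all0$near_fraction, 1)
  expect_equal(all0$ecdf(0), 1)
  d <- c(1, 3, 7, 9)
  s <- distance_summary(d, bin_um = 2, near_radius_um = 5)
  expect_equal(s$near_fraction, 0.5)
  # density-normalized histogram has unit area for random inputs
  set.seed(88)
  r <- rexp(500, 0.2)
  sr <- distance_summary(r, bin_um = 2)
  expect_equal(sum(sr$density) * 2, 1)
  # per-video SEM of the near fraction
  vid <- rep(1:5, each = 100)
  dv <- runif(500, 0, 20)
  sv <- distance_summary(dv, video = vid)
  per <- tapply(dv <= 5, vid, mean)
  expect_equal(sv$near_fraction_sem, sd(per) / sqrt(5))
})

test_that("lumen-enriched scenes show the near-lumen excess", {
  mspec <- mnr_spec(n_puncta = 300, n_blobs = 0, n_spurious = 0, n_frames = 1,
                    lumen_radius_um = 3, outer_radius_um = 12,
                    lumen_enrichment = 0.7, enrichment_scale_um = 2,
                    image_size_px = 256, seed = 120)
  scene <- simulate_mnr_scene(mspec)
  tp <- scene$truth[scene$truth$type == "punctum", ]
  dist <- distances_to_masks(
    data.frame(x_nm = tp$x_um * 1000, y_nm = tp$y_um * 1000),
    scene$lumen_mask, scene$outer_mask, 0.108)
  near_lumen <- mean(dist$d_lumen_um <= 5)
  near_outer <- mean(dist$d_outer_um <= 5)
  expect_gt(near_lumen, near_outer)
  expect_gt(near_lumen, 0.5)   # enrichment concentrates puncta at the lumen
})
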