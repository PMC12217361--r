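# Independent brute-force oracles and small fixture builders.

# all-ordered-pairs time-averaged MSD, written independently of compute_msd()
brute_msd <- function(x_um, y_um, dt, max_lag_s) {
  n <- length(x_um)
  kmax <- min(n - 1, floor(max_lag_s / dt))
  data.frame(
    lag_s = (1:kmax) * dt,
    msd_um2 = sapply(1:kmax, function(k) {
      vals <- numeric(0)
      for (i in 1:(n - k))
        vals <- c(vals, (x_um[i + k] - x_um[i])^2 + (y_um[i + k] - y_um[i])^2)
      mean(vals)
    }))
}

# exhaustive nearest-mask-pixel search, pixel units (pre-ceil)
brute_mask_distance_px <- function(mask, row, col) {
  px <- which(mask, arr.ind = TRUE)
  min(sqrt((px[, 1] - row)^2 + (px[, 2] - col)^2))
}

# build a trajectory data.frame from micrometre coordinates
make_traj <- function(x_um, y_um, track_id = 1L,
                      frame = seq_along(x_um) - 1L,
                      interpolated = rep(FALSE, length(x_um))) {
  data.frame(track_id = track_id, frame = frame,
             x_nm = x_um * 1000, y_nm = y_um * 1000,
             interpolated = interpolated)
}

# build an intensity-trace data.frame directly
make_trace <- function(values, dt = 0.1, track_id = 1L) {
  data.frame(track_id = track_id, frame = seq_along(values) - 1L,
             t_s = (seq_along(values) - 1L) * dt,
             intensity_cu = values,
             interpolated = rep(FALSE, length(values)))
}

# localization table of n well-separated static puncta on a jittered grid,
# detected in every one of `n_frames` frames (no rendering involved)
grid_localizations <- function(n_side = 5, n_frames = 50, spacing_px = 8,
                               jitter_px = 0.3, pixel_size_um = 0.108,
                               sigma_nm = 189, intensity = 900, seed = 7) {
  set.seed(seed)
  px_nm <- pixel_size_um * 1000
  centres <- expand.grid(cx = (1:n_side) * spacing_px,
                         cy = (1:n_side) * spacing_px)
  out <- list()
  for (f in 0:(n_frames - 1)) {
    out[[f + 1]] <- data.frame(
      punctum = seq_len(nrow(centres)), frame = f,
      x_nm = (centres$cx + rnorm(nrow(centres), sd = jitter_px)) * px_nm,
      y_nm = (centres$cy + rnorm(nrow(centres), sd = jitter_px)) * px_nm,
      sigma_nm = sigma_nm, intensity_photons = intensity,
      background_photons = 1)
  }
  do.call(rbind, out)
}
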