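#' Single lag displacements of a track
#'
#' Euclidean distances (in micrometres) moved between consecutive frames of
#' one track, interpolated gap-frame positions included.
#'
#' @param traj trajectory data.frame rows of a single track.
#' @return numeric vector of SLDs (um); empty for tracks shorter than 2 rows.
#' @export
compute_sld <- function(traj) {
  if (length(unique(traj$track_id)) > 1)
    stopf("compute_sld expects a single track; see sld_by_track()")
  traj <- traj[order(traj$frame), ]
  if (nrow(traj) < 2) return(numeric(0))
  sqrt(diff(traj$x_nm)^2 + diff(traj$y_nm)^2) / 1000
}

#' @rdname compute_sld
#' @param trajs multi-track trajectory data.frame.
#' @return `sld_by_track`: named list of SLD vectors, one per track.
#' @export
sld_by_track <- function(trajs) lapply(split_tracks(trajs), compute_sld)

#' Fit exponential mixtures to the CDF of squared displacements
#'
#' Fits the empirical CDF of SLD^2 values to
#' `1 - sum(a_i * exp(-x / lambda_i))` with the weights summing to one, by
#' nonlinear least squares at the sorted sample points. For a single Brownian
#' population the one-component fit suffices (`lambda = 4*D*dt + 4*sigma_loc^2`);
#' a materially lower two-component residual indicates a mobility mixture.
#'
#' @param sld_sq squared displacements, um^2 (>= 50 values).
#' @param n_components 1 or 2.
#' @return list of class `mixture_fit`: `model` ("exp1"/"exp2"), `weights`,
#'   `scales` (um^2), `rss`, and the fitted CDF values.
#' @export
fit_sld_cdf <- function(sld_sq, n_components = 2) {
  sld_sq <- sld_sq[!is.na(sld_sq)]
  if (length(sld_sq) < 50) stopf("need at least 50 squared displacements")
  if (all(sld_sq == 0)) stopf("degenerate input: all squared displacements are 0")
  x <- sort(sld_sq)
  n <- length(x)
  df <- data.frame(x = x, F = seq_len(n) / n)
  m <- mean(x)
  if (n_components == 1) {
    fit <- minpack.lm::nlsLM(F ~ 1 - exp(-x / l1), data = df,
                             start = list(l1 = m),
                             lower = c(l1 = 1e-12))
    co <- coef(fit)
    weights <- 1; scales <- unname(co["l1"]); model <- "exp1"
  } else if (n_components == 2) {
    # multi-start: component collapse (l1 ~ l2) makes the Jacobian singular
    # on one-population data, so several initial splits are attempted
    starts <- list(list(a = 0.5, l1 = 0.3 * m, l2 = 3 * m),
                   list(a = 0.3, l1 = 0.5 * m, l2 = 2 * m),
                   list(a = 0.7, l1 = 0.1 * m, l2 = 1.5 * m),
                   list(a = 0.5, l1 = 0.9 * m, l2 = 1.2 * m))
    fit <- NULL
    for (st in starts) {
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nlsLM(
          F ~ 1 - (a * exp(-x / l1) + (1 - a) * exp(-x / l2)),
          data = df, start = st,
          lower = c(a = 0, l1 = 1e-12, l2 = 1e-12),
          upper = c(a = 1, l1 = Inf, l2 = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stopf(paste0("two-component CDF fit did not converge from any start ",
                   "(last init a=0.5, lambda=%.3g/%.3g)"), 0.9 * m, 1.2 * m)
    co <- coef(fit)
    weights <- c(co["a"], 1 - co["a"]); scales <- c(co["l1"], co["l2"])
    o <- order(scales)
    weights <- unname(weights[o]); scales <- unname(scales[o])
    model <- "exp2"
  } else stopf("n_components must be 1 or 2")
  structure(list(model = model, weights = weights, scales = scales,
                 rss = sum(residuals(fit)^2), fitted = fitted(fit)),
            class = "mixture_fit")
}

#' Path length of tracks over a fixed window
#'
#' Total distance travelled (sum of SLDs, interpolated segments included) over
#' the first `window_s` of each track: the first `round(window_s / dt)` frames,
#' e.g. 50 frames (49 segments) for a 5 s window at 10 fps. Tracks shorter
#' than the window are excluded (`NA` path) and counted in the log.
#'
#' @param trajs trajectory data.frame (one or more tracks).
#' @param window_s window length, seconds.
#' @param frame_interval_s frame interval of the movie, seconds.
#' @return data.frame `track_id`, `path_um` (NA when the track is shorter
#'   than the window).
#' @export
path_lengths <- function(trajs, window_s = 5, frame_interval_s) {
  n_win <- as.integer(round(window_s / frame_interval_s))
  if (n_win < 2) stopf("window shorter than two frames")
  tracks <- split_tracks(trajs)
  path <- vapply(tracks, function(tr) {
    if (nrow(tr) < n_win) return(NA_real_)
    sum(compute_sld(tr[seq_len(n_win), ]))
  }, numeric(1))
  n_short <- sum(is.na(path))
  pt_log("path length at %g s: %d tracks, %d excluded as shorter than window",
         window_s, length(path), n_short)
  data.frame(track_id = as.integer(names(tracks)), path_um = unname(path))
}

#' Two-component Gaussian fit to a path-length distribution
#'
#' Fits the binned relative-frequency histogram of path lengths to a sum of
#' two Gaussians; components are ordered by mean. Used to separate the
#' immobile peak (apparent motion from localization error) from the mobile
#' population before choosing a cutoff.
#'
#' @param paths path lengths, um (>= 100 non-NA values).
#' @param n_bins histogram bin count.
#' @return list of class `mixture_fit`: `model = "gauss2"`, `weights`,
#'   `means`, `sds`, `rss`.
#' @export
fit_path_length_mixture <- function(paths, n_bins = 40) {
  paths <- paths[!is.na(paths)]
  if (length(paths) < 100) stopf("need at least 100 path lengths")
  if (diff(range(paths)) == 0) stopf("degenerate input: constant path lengths")
  h <- graphics::hist(paths, breaks = n_bins, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts / sum(h$counts))
  q <- quantile(paths, c(0.25, 0.75))
  s0 <- sd(paths) / 2
  a0 <- max(df$y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
          a2 * exp(-(x - m2)^2 / (2 * s2^2)),
      data = df,
      start = list(a1 = a0, m1 = q[[1]], s1 = s0,
                   a2 = a0 / 2, m2 = q[[2]], s2 = s0),
      lower = c(a1 = 0, m1 = -Inf, s1 = 1e-6, a2 = 0, m2 = -Inf, s2 = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stopf("two-Gaussian fit did not converge: %s",
                              conditionMessage(e)))
  co <- coef(fit)
  means <- c(co["m1"], co["m2"]); sds <- c(co["s1"], co["s2"])
  mass <- c(co["a1"], co["a2"]) * sds          # ~ component areas
  o <- order(means)
  structure(list(model = "gauss2",
                 weights = unname(mass[o] / sum(mass)),
                 means = unname(means[o]), sds = unname(sds[o]),
                 rss = sum(residuals(fit)^2)),
            class = "mixture_fit")
}

#' Classify track mobility by path length
#'
#' Path length strictly greater than `cutoff_um` over the standard window is
#' "mobile", otherwise "immobile" (the 3 um default largely excludes tracks
#' whose apparent motion is localization error).
#'
#' @param path_um path length(s) at the standard window, um.
#' @param cutoff_um strict cutoff (default 3 um at 5 s).
#' @return character vector of labels ("mobile"/"immobile", NA preserved).
#' @export
classify_mobility <- function(path_um, cutoff_um = 3) {
  ifelse(is.na(path_um), NA_character_,
         ifelse(path_um > cutoff_um, "mobile", "immobile"))
}

#' Time-averaged mean squared displacement per track
#'
#' For each lag `k*dt` up to `max_lag_s`, averages the squared displacement
#' over all ordered within-track frame pairs `(i, i+k)` (the standard
#' time-averaged estimator for short single-particle tracks).
#'
#' @param trajs trajectory data.frame.
#' @param frame_interval_s frame interval, seconds.
#' @param max_lag_s largest lag computed, seconds.
#' @return data.frame `track_id`, `lag_s`, `msd_um2`.
#' @export
compute_msd <- function(trajs, frame_interval_s, max_lag_s = 5) {
  kmax_global <- max(1L, as.integer(floor(max_lag_s / frame_interval_s)))
  tracks <- split_tracks(trajs)
  out <- lapply(tracks, function(tr) {
    if (nrow(tr) < 2) return(NULL)
    x <- tr$x_nm / 1000; y <- tr$y_nm / 1000
    kmax <- min(kmax_global, nrow(tr) - 1L)
    msd <- vapply(seq_len(kmax), function(k) {
      i <- seq_len(nrow(tr) - k)
      mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
    }, numeric(1))
    data.frame(track_id = tr$track_id[1], lag_s = seq_len(kmax) * frame_interval_s,
               msd_um2 = msd)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean MSD curve across tracks
#'
#' Unweighted mean of per-track MSD values at each lag (every track counts
#' equally, as when averaging per-video mean MSD traces).
#'
#' @param msd data.frame from [compute_msd()].
#' @return data.frame `lag_s`, `msd_um2`, `n_tracks`.
#' @export
mean_msd <- function(msd) {
  agg <- aggregate(msd_um2 ~ lag_s, data = msd, FUN = mean)
  agg$n_tracks <- aggregate(msd_um2 ~ lag_s, data = msd, FUN = length)$msd_um2
  agg[order(agg$lag_s), ]
}

#' Apparent diffusion coefficient from an MSD curve
#'
#' Linear fit (free intercept, absorbing the localization-error offset) of
#' `MSD = 4*D*lag + b` over lags up to `fit_max_lag_s`; `D = slope / 4`.
#' A negative slope is clamped to `D = 0` with a warning.
#'
#' @param msd_curve data.frame with `lag_s` and `msd_um2` (e.g. from
#'   [mean_msd()]).
#' @param fit_max_lag_s maximum lag included in the fit (default 2 s).
#' @return list `D_um2_s`, `slope`, `intercept`, `n_points`.
#' @export
fit_diffusion <- function(msd_curve, fit_max_lag_s = 2) {
  d <- msd_curve[msd_curve$lag_s <= fit_max_lag_s + 1e-9, ]
  if (nrow(d) < 3) stopf("need at least 3 lag points within the fit range")
  fit <- lm(msd_um2 ~ lag_s, data = d)
  slope <- unname(coef(fit)[2])
  D <- slope / 4
  if (D < 0) {
    warnf("negative MSD slope (%.3g); apparent D clamped to 0", slope)
    D <- 0
  }
  list(D_um2_s = D, slope = slope, intercept = unname(coef(fit)[1]),
       n_points = nrow(d))
}

#' Full mobility summary of a set of tracks
#'
#' Convenience wrapper: per-track MSD curves, the per-video mean MSD, its
#' linear-fit diffusion estimate, per-track path lengths at the standard
#' window and the mobile/immobile classification.
#'
#' @param trajs trajectory data.frame.
#' @param frame_interval_s frame interval, seconds.
#' @param config a [pipeline_config()].
#' @param max_lag_s largest MSD lag, seconds.
#' @return list `msd`, `mean_msd`, `diffusion`, `paths` (with `class` column).
#' @export
compute_msd_and_D <- function(trajs, frame_interval_s,
                              config = pipeline_config(), max_lag_s = 5) {
  msd <- compute_msd(trajs, frame_interval_s, max_lag_s)
  mm <- mean_msd(msd)
  fit <- fit_diffusion(mm, config$msd_fit_max_lag_s)
  paths <- path_lengths(trajs, config$path_window_s, frame_interval_s)
  paths$class <- classify_mobility(paths$path_um, config$mobility_cutoff_um)
  list(msd = msd, mean_msd = mm, diffusion = fit, paths = paths)
}

#' Localization error from fixed-sample tracks
#'
#' For immobilized (fixed-sample) puncta, the radial distance of each
#' localization from its track's mean position estimates the localization
#' error; reported as mean +/- SEM over all localizations.
#'
#' @param trajs trajectory data.frame of fixed-sample tracks (interpolated
#'   rows are ignored).
#' @return list `mean_nm`, `sem_nm`, `distances_nm` (per localization).
#' @export
localization_error <- function(trajs) {
  det <- trajs[!trajs$interpolated, ]
  dists <- unlist(lapply(split_tracks(det), function(tr) {
    sqrt((tr$x_nm - mean(tr$x_nm))^2 + (tr$y_nm - mean(tr$y_nm))^2)
  }), use.names = FALSE)
  list(mean_nm = mean(dists), sem_nm = sem(dists), distances_nm = dists)
}

#' Photobleaching time constant
#'
#' Least-squares fit of `A * exp(-t / tau) + C` to a mean puncta-intensity
#' time series (e.g. from [bleach_trace()]). A non-decaying trace yields a
#' non-finite `tau_s` with a warning rather than an error.
#'
#' @param intensity intensity values (camera units or photons).
#' @param time_s matching time points, seconds.
#' @return list `tau_s`, `tau_se`, `A`, `C`.
#' @export
bleach_time_constant <- function(intensity, time_s) {
  stopifnot(length(intensity) == length(time_s))
  C0 <- min(intensity)
  A0 <- max(intensity) - C0
  if (A0 <= 0) {
    warnf("intensity trace does not decay; tau reported as NA")
    return(list(tau_s = NA_real_, tau_se = NA_real_, A = NA_real_, C = C0))
  }
  # initial tau from a log-linear fit of the above-floor excess
  excess <- pmax(intensity - C0, A0 * 1e-3)
  sl <- unname(coef(lm(log(excess) ~ time_s))[2])
  if (!is.finite(sl) || sl >= 0) {
    warnf("intensity trace does not decay; tau reported as NA")
    return(list(tau_s = NA_real_, tau_se = NA_real_, A = NA_real_, C = C0))
  }
  df <- data.frame(I = intensity, t = time_s)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ A * exp(-t / tau) + C, data = df,
                      start = list(A = A0, tau = -1 / sl, C = C0),
                      lower = c(A = 0, tau = 1e-9, C = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warnf("exponential fit did not converge; tau reported as NA")
    return(list(tau_s = NA_real_, tau_se = NA_real_, A = NA_real_, C = C0))
  }
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  list(tau_s = unname(co["tau"]), tau_se = unname(se),
       A = unname(co["A"]), C = unname(co["C"]))
}

#' Mean puncta intensity per frame
#'
#' Averages background-subtracted 3x3-ROI intensity traces
#' (see [extract_intensity_trace()]) over tracked puncta, giving the
#' per-frame mean intensity series used for bleach fitting.
#'
#' @param movie a [movie_stack()].
#' @param trajs trajectory data.frame.
#' @param background_roi background ROI centre `c(x_px, y_px)`, 0-based.
#' @return data.frame `frame`, `t_s`, `intensity_cu` (mean over puncta
#'   present in that frame).
#' @export
bleach_trace <- function(movie, trajs, background_roi) {
  traces <- lapply(split_tracks(trajs), function(tr)
    extract_intensity_trace(movie, tr, background_roi))
  all <- do.call(rbind, traces)
  agg <- aggregate(intensity_cu ~ frame, data = all, FUN = mean)
  agg$t_s <- agg$frame * movie$frame_interval_s
  agg[order(agg$frame), c("frame", "t_s", "intensity_cu")]
}

#' Signal-to-background ratio of detected puncta
#'
#' Per punctum: mean of the 3x3 pixel ROI at the punctum centre divided by the
#' mean of a punctum-free 3x3 background ROI, both after subtracting the
#' camera black level, measured on the punctum's frame.
#'
#' @param movie a [movie_stack()].
#' @param locs localization data.frame (typically first-frame detections).
#' @param background_roi background ROI centre `c(x_px, y_px)`, 0-based; must
#'   be at least 3 px away from every detection.
#' @return list `ratios`, `mean`, `sem`.
#' @export
signal_to_background <- function(movie, locs, background_roi) {
  px_nm <- movie$pixel_size_um * 1000
  bx <- background_roi[1]; by <- background_roi[2]
  too_close <- abs(locs$x_nm / px_nm - bx) < 3 & abs(locs$y_nm / px_nm - by) < 3
  if (any(too_close))
    stopf("background ROI overlaps %d detection(s)", sum(too_close))
  ratios <- vapply(seq_len(nrow(locs)), function(i) {
    img <- get_frame(movie, locs$frame[i])
    sig <- roi_mean(img, locs$x_nm[i] / px_nm, locs$y_nm[i] / px_nm) -
      movie$black_level_cu
    bg <- roi_mean(img, bx, by) - movie$black_level_cu
    if (bg <= 0)
      stopf("background ROI is at or below the black level; ratio undefined")
    sig / bg
  }, numeric(1))
  list(ratios = ratios, mean = mean(ratios), sem = sem(ratios))
}

# mean over the 3x3 pixel ROI centred on the rounded (x, y) pixel position
roi_mean <- function(img, x_px, y_px) {
  r <- round(y_px) + 1L; c <- round(x_px) + 1L
  if (r < 2 || r > nrow(img) - 1 || c < 2 || c > ncol(img) - 1)
    stopf("3x3 ROI at (%g, %g) px violates the 1-px frame margin", x_px, y_px)
  mean(img[(r - 1):(r + 1), (c - 1):(c + 1)])
}
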