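#' Extract a background-subtracted punctum intensity trace
#'
#' For each detected frame of one track: sum of the 3x3 pixel window centred
#' on the rounded punctum position minus the 3x3 sum at the background ROI in
#' the same frame (the camera black level cancels in the subtraction). Gap
#' frames are filled by linear interpolation of the intensity and flagged.
#' Frames whose ROI would violate the 1-px margin are dropped (trace
#' truncated) with a warning.
#'
#' @param movie a [movie_stack()].
#' @param traj trajectory data.frame of one track.
#' @param background_roi background ROI centre `c(x_px, y_px)`, 0-based,
#'   inside a punctum-free region.
#' @return data.frame `track_id`, `frame`, `t_s`, `intensity_cu`,
#'   `interpolated`.
#' @export
extract_intensity_trace <- function(movie, traj, background_roi) {
  if (length(unique(traj$track_id)) > 1)
    stopf("extract_intensity_trace expects a single track")
  px_nm <- movie$pixel_size_um * 1000
  traj <- traj[order(traj$frame), ]
  nr <- dim(movie$data)[2]; nc <- dim(movie$data)[3]
  det <- traj[!traj$interpolated, ]
  vals <- rep(NA_real_, nrow(det))
  for (i in seq_len(nrow(det))) {
    r <- round(det$y_nm[i] / px_nm) + 1L
    c <- round(det$x_nm[i] / px_nm) + 1L
    if (r < 2 || r > nr - 1 || c < 2 || c > nc - 1) next  # margin violation
    img <- get_frame(movie, det$frame[i])
    sig <- sum(img[(r - 1):(r + 1), (c - 1):(c + 1)])
    bg <- 9 * roi_mean(img, background_roi[1], background_roi[2])
    vals[i] <- sig - bg
  }
  if (anyNA(vals)) {
    warnf("trace truncated: %d frame(s) violate the 1-px ROI margin",
          sum(is.na(vals)))
    det <- det[!is.na(vals), ]; vals <- vals[!is.na(vals)]
  }
  if (!nrow(det))
    return(data.frame(track_id = integer(), frame = integer(), t_s = numeric(),
                      intensity_cu = numeric(), interpolated = logical()))
  frames <- min(det$frame):max(det$frame)
  intensity <- if (nrow(det) == 1) vals else
    stats::approx(det$frame, vals, xout = frames)$y
  data.frame(track_id = traj$track_id[1], frame = frames,
             t_s = frames * movie$frame_interval_s,
             intensity_cu = intensity,
             interpolated = !(frames %in% det$frame))
}

#' All-points amplitude histogram
#'
#' Histogram of every frame's amplitude across one or more intensity traces.
#' With `average = FALSE` the counts are pooled (their sum equals the total
#' number of frames); with `average = TRUE` each punctum's relative-frequency
#' histogram on shared bin edges is averaged with equal punctum weight, so
#' each punctum contributes unit mass. Such histograms expose the discrete
#' dim/bright intensity levels of flickering Ca2+-reporter puncta and are
#' conventionally displayed with log10 counts.
#'
#' @param traces one trace data.frame or a list of them (shared frame
#'   interval).
#' @param bin_width_cu bin width in camera units (default 1).
#' @param average average per-punctum relative frequencies instead of pooling
#'   counts.
#' @return list of class `amplitude_histogram`: `breaks`, `mids`, `counts`
#'   (pooled counts, or mean relative frequencies when averaged), `n_traces`,
#'   `average`.
#' @export
all_points_histogram <- function(traces, bin_width_cu = 1, average = FALSE) {
  if (is.data.frame(traces)) traces <- list(traces)
  if (!length(traces) || !sum(vapply(traces, nrow, 1L)))
    stopf("no trace data for the amplitude histogram")
  amps <- lapply(traces, function(tr) tr$intensity_cu)
  rng <- range(unlist(amps))
  lo <- floor(rng[1] / bin_width_cu) * bin_width_cu
  hi <- ceiling((rng[2] + 1e-9) / bin_width_cu) * bin_width_cu
  breaks <- seq(lo, hi, by = bin_width_cu)
  if (length(breaks) < 2) breaks <- c(lo, lo + bin_width_cu)
  count_one <- function(a)
    graphics::hist(a, breaks = breaks, plot = FALSE, right = FALSE)$counts
  per <- lapply(amps, count_one)
  counts <- if (average) {
    rel <- lapply(per, function(cnt) cnt / sum(cnt))
    Reduce(`+`, rel) / length(rel)
  } else {
    Reduce(`+`, per)
  }
  structure(list(breaks = breaks, mids = head(breaks, -1) + bin_width_cu / 2,
                 counts = counts, n_traces = length(traces),
                 average = average),
            class = "amplitude_histogram")
}

#' Puncta density in a region of interest
#'
#' Count of puncta detected in one frame divided by the region area. Per-video
#' densities are conventionally aggregated as mean +/- SEM with
#' [density_summary()].
#'
#' @param locs localization data.frame, or a bare count.
#' @param roi_area_um2 region area, um^2 (> 0).
#' @param frame 0-based frame whose detections are counted (default the first
#'   frame, after any temporal binning).
#' @return density in puncta per um^2.
#' @export
puncta_density <- function(locs, roi_area_um2, frame = 0) {
  if (roi_area_um2 <= 0) stopf("roi_area_um2 must be > 0")
  n <- if (is.data.frame(locs)) sum(locs$frame == frame) else as.numeric(locs)
  n / roi_area_um2
}

#' @rdname puncta_density
#' @param densities per-video densities.
#' @return `density_summary`: list `mean`, `sem`, `n`.
#' @export
density_summary <- function(densities) {
  list(mean = mean(densities), sem = sem(densities), n = length(densities))
}

#' Detect flicker events in an intensity trace
#'
#' Events are contiguous excursions of a background-subtracted trace above a
#' robust threshold: `baseline + k * sigma`, with the baseline the trace
#' median and `sigma` a MAD-type scale estimated from the dim (at/below
#' baseline) portion of the trace. For each event the rise/fall frames,
#' duration, peak amplitude, and the frame counts needed to reach 90% of the
#' peak on each flank are reported.
#'
#' @param trace trace data.frame from [extract_intensity_trace()].
#' @param k threshold in dim-noise SD units (default 4).
#' @param frame_interval_s frame interval; taken from the trace `t_s` column
#'   when omitted.
#' @return data.frame with one row per event: `rise_frame`, `fall_frame`,
#'   `duration_frames`, `duration_s`, `amplitude`, `rise_n`, `fall_n`.
#' @export
flicker_dwell_stats <- function(trace, k = 4, frame_interval_s = NULL) {
  v <- trace$intensity_cu
  if (is.null(frame_interval_s))
    frame_interval_s <- if (nrow(trace) > 1) diff(trace$t_s[1:2]) else 1
  base <- median(v)
  dim_dev <- v[v <= base] - base
  sigma <- 1.4826 * median(abs(dim_dev))
  if (!is.finite(sigma) || sigma == 0) sigma <- 1e-9
  thr <- base + k * sigma
  above <- v > thr
  if (!any(above))
    return(data.frame(rise_frame = integer(), fall_frame = integer(),
                      duration_frames = integer(), duration_s = numeric(),
                      amplitude = numeric(), rise_n = integer(),
                      fall_n = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- which(r$values)
  out <- lapply(ev, function(e) {
    i0 <- starts[e]; i1 <- ends[e]
    seg <- v[i0:i1]
    peak <- max(seg)
    rise_n <- which(seg >= base + 0.9 * (peak - base))[1]
    fall_n <- (i1 - i0 + 1L) - tail(which(seg >= base + 0.9 * (peak - base)), 1) + 1L
    data.frame(rise_frame = trace$frame[i0], fall_frame = trace$frame[i1],
               duration_frames = i1 - i0 + 1L,
               duration_s = (i1 - i0 + 1L) * frame_interval_s,
               amplitude = peak - base, rise_n = rise_n, fall_n = fall_n)
  })
  do.call(rbind, out)
}

#' Cohen's d effect size
#'
#' Classic pooled-SD form without small-sample correction:
#' `d = (m1 - m2) / s_p` with
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param x,y raw samples.
#' @return Cohen's d (first group minus second).
#' @export
cohens_d <- function(x, y) {
  cohens_d_summary(mean(x), sd(x) / sqrt(length(x)), length(x),
                   mean(y), sd(y) / sqrt(length(y)), length(y))
}

#' @rdname cohens_d
#' @param m1,sem1,n1,m2,sem2,n2 group summaries (mean, SEM, n); the SD is
#'   recovered as `SEM * sqrt(n)`.
#' @export
cohens_d_summary <- function(m1, sem1, n1, m2, sem2, n2) {
  s1 <- sem1 * sqrt(n1); s2 <- sem2 * sqrt(n2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

#' Two-group condition comparison
#'
#' Normality is checked per group (Shapiro-Wilk at alpha = 0.05); normally
#' distributed groups are compared with the two-sided two-sample t test,
#' otherwise with the two-sided Mann-Whitney test. Cohen's d (pooled SD) is
#' always reported.
#'
#' @param x,y per-video or per-punctum scalars (each n >= 2).
#' @return list `test` ("t" or "mann-whitney"), `p_value`, `cohens_d`,
#'   `normal` (per-group logical), `means`.
#' @export
condition_compare <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("each group needs n >= 2")
  is_normal <- function(v) {
    if (length(v) < 3 || sd(v) == 0) return(FALSE)
    shapiro.test(v)$p.value > 0.05
  }
  normal <- c(is_normal(x), is_normal(y))
  if (all(normal)) {
    ht <- t.test(x, y, var.equal = TRUE); test <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y)); test <- "mann-whitney"
  }
  list(test = test, p_value = ht$p.value, cohens_d = cohens_d(x, y),
       normal = normal, means = c(mean(x), mean(y)))
}

#' Two-sample Kolmogorov-Smirnov comparison of amplitude distributions
#'
#' Compares the frame-amplitude distributions of two traces (or pooled trace
#' sets), as used for all-points amplitude histograms across conditions.
#'
#' @param x,y numeric amplitude samples, or trace data.frames.
#' @return the `ks.test` result.
#' @export
compare_amplitudes_ks <- function(x, y) {
  if (is.data.frame(x)) x <- x$intensity_cu
  if (is.data.frame(y)) y <- y$intensity_cu
  suppressWarnings(ks.test(x, y))
}
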