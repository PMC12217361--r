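#' Detection parameters
#'
#' Controls the per-frame spot detector: a difference-of-Gaussians band-pass,
#' a threshold in units of the robust (MAD-based) background SD, and the
#' window size of the least-squares Gaussian fit. The detector is a stated
#' stand-in for ThunderSTORM's wavelet pipeline, validated against simulated
#' ground truth rather than against ThunderSTORM output.
#'
#' @param dog_sigmas two Gaussian blur SDs in pixels (narrow, wide) for the
#'   band-pass.
#' @param threshold_k detection threshold in robust-SD units of the band-pass
#'   response.
#' @param fit_box_px odd fitting-window edge, >= 5 pixels.
#' @param sigma_max_nm PSF-width filter bound used by [sigma_filter()].
#' @param bin_factor temporal binning factor applied before detection.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(dog_sigmas = c(1, 2), threshold_k = 5,
                             fit_box_px = 9, sigma_max_nm = 280,
                             bin_factor = 1) {
  if (fit_box_px < 5 || fit_box_px %% 2 == 0)
    stopf("fit_box_px must be odd and >= 5")
  if (threshold_k <= 0) stopf("threshold_k must be > 0")
  structure(list(dog_sigmas = dog_sigmas, threshold_k = threshold_k,
                 fit_box_px = fit_box_px, sigma_max_nm = sigma_max_nm,
                 bin_factor = bin_factor),
            class = "detection_params")
}

#' Temporally bin a movie
#'
#' Averages each run of `factor` consecutive frames into one output frame
#' (mean, not sum, preserving the camera-unit scale used by intensity
#' thresholds); the frame interval is multiplied by `factor` and trailing
#' remainder frames are dropped. Used e.g. to bin 100 fps acquisitions to
#' 10 fps before density analysis.
#'
#' @param movie a [movie_stack()].
#' @param factor integer >= 1.
#' @return A [movie_stack()].
#' @export
temporal_bin <- function(movie, factor) {
  if (factor < 1) stopf("binning factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(movie)
  nf <- n_frames(movie) %/% factor
  if (nf == 0) stopf("movie has fewer frames than the binning factor")
  d <- dim(movie$data)
  out <- array(0, dim = c(nf, d[2], d[3]))
  for (i in seq_len(nf)) {
    idx <- ((i - 1L) * factor + 1L):(i * factor)
    out[i, , ] <- apply(movie$data[idx, , , drop = FALSE], c(2, 3), mean)
  }
  movie_stack(out, movie$pixel_size_um, movie$frame_interval_s * factor,
              movie$gain_pe_per_cu, movie$black_level_cu)
}

# 8-neighbourhood local maxima of a matrix; half the comparisons are strict so
# flat plateaus yield a single detection.
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  shift <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  m > shift(-1, -1) & m > shift(-1, 0) & m > shift(-1, 1) & m > shift(0, -1) &
    m >= shift(0, 1) & m >= shift(1, -1) & m >= shift(1, 0) & m >= shift(1, 1)
}

# Integrated-Gaussian least-squares fit of one spot in a square window.
# `win` is the camera-unit sub-image, (row0, col0) its 0-based origin.
# Returns NULL on failure to converge.
fit_spot <- function(win, row0, col0) {
  nr <- nrow(win); nc <- ncol(win)
  rows <- row0 + (0:(nr - 1)); cols <- col0 + (0:(nc - 1))
  b0 <- min(win)
  w0 <- pmax(win - b0, 0)
  tot <- sum(w0)
  if (tot <= 0) return(NULL)
  x0 <- sum(t(w0) * cols) / tot
  y0 <- sum(w0 * rows) / tot
  df <- data.frame(v = as.vector(win),
                   r = rep(rows, times = nc), c = rep(cols, each = nr))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * (pnorm(c + 0.5, x, s) - pnorm(c - 0.5, x, s)) *
        (pnorm(r + 0.5, y, s) - pnorm(r - 0.5, y, s)) + b,
      data = df,
      start = list(A = tot, x = x0, y = y0, s = 1.3, b = b0),
      lower = c(A = 0, x = col0 - 0.5, y = row0 - 0.5, s = 0.3,
                b = -Inf),
      upper = c(A = Inf, x = col0 + nc - 0.5, y = row0 + nr - 0.5,
                s = max(nr, nc), b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.list(coef(fit))
}

#' Detect and localize puncta in every frame
#'
#' Per frame: difference-of-Gaussians band-pass, local maxima above
#' `threshold_k` robust SDs (median absolute deviation) of the band-pass
#' response, then least-squares fitting of a symmetric integrated 2-D Gaussian
#' (amplitude, x, y, sigma, offset) in a `fit_box_px` window around each
#' candidate. Intensities are converted to photoelectrons via the movie gain;
#' fits that fail to converge are dropped and counted in the log.
#'
#' @param movie a [movie_stack()].
#' @param params a [detection_params()].
#' @return A localization data.frame (see [localization_table()]), possibly
#'   empty.
#' @export
detect_and_localize <- function(movie, params = detection_params()) {
  if (params$bin_factor > 1) movie <- temporal_bin(movie, params$bin_factor)
  px_nm <- movie$pixel_size_um * 1000
  half <- (params$fit_box_px - 1L) %/% 2L
  nr <- dim(movie$data)[2]; nc <- dim(movie$data)[3]
  res <- list(); n_failed <- 0L
  for (f in 0:(n_frames(movie) - 1)) {
    img <- get_frame(movie, f)
    dog <- as.matrix(EBImage::gblur(img, params$dog_sigmas[1])) -
      as.matrix(EBImage::gblur(img, params$dog_sigmas[2]))
    thr <- median(dog) + params$threshold_k * mad(dog)
    cand <- which(local_maxima(dog) & dog > thr, arr.ind = TRUE)
    if (!nrow(cand)) next
    # keep candidates whose fit window lies inside the frame
    ok <- cand[, 1] > half & cand[, 1] <= nr - half &
      cand[, 2] > half & cand[, 2] <= nc - half
    cand <- cand[ok, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      r <- cand[j, 1]; c <- cand[j, 2]
      win <- img[(r - half):(r + half), (c - half):(c + half)]
      co <- fit_spot(win, r - half - 1L, c - half - 1L)
      if (is.null(co)) { n_failed <- n_failed + 1L; next }
      res[[length(res) + 1L]] <- data.frame(
        frame = f, x_nm = co$x * px_nm, y_nm = co$y * px_nm,
        sigma_nm = co$s * px_nm,
        intensity_photons = co$A * movie$gain_pe_per_cu,
        background_photons = max(co$b - movie$black_level_cu, 0) *
          movie$gain_pe_per_cu)
    }
  }
  locs <- if (length(res)) do.call(rbind, res) else localization_table()
  pt_log("detected %d localizations in %d frames (%d failed fits)",
         nrow(locs), n_frames(movie), n_failed)
  locs
}

#' Filter localizations on fitted PSF width
#'
#' Removes detections with fitted Gaussian SD strictly greater than
#' `sigma_max_nm` (the boundary is kept): large autofluorescent blobs fail
#' this filter while diffraction-limited puncta (bead-calibrated SD ~189 nm)
#' pass the default 280 nm bound.
#'
#' @param locs localization data.frame.
#' @param sigma_max_nm inclusive upper bound on `sigma_nm`.
#' @return The filtered localization data.frame.
#' @export
sigma_filter <- function(locs, sigma_max_nm = 280) {
  keep <- locs$sigma_nm <= sigma_max_nm
  pt_log("sigma filter: kept %d of %d localizations (sigma <= %g nm)",
         sum(keep), nrow(locs), sigma_max_nm)
  locs[keep, , drop = FALSE]
}
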