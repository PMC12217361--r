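#' Filter organoid detections to bona fide puncta
#'
#' Two filtering paths mirror the two labelling chemistries:
#' \describe{
#'   \item{`static_label`}{(always-bright ligand, e.g. JF635): PSF-width
#'     filter (`sigma <= sigma_max_nm`), nearest-neighbour linking with a
#'     3-pixel radius and a one-frame gap, persistence filter keeping tracks
#'     detected in at least 4 frames (3 linked segments), then each surviving
#'     track reduced to the mean position of its detected localizations.}
#'   \item{`calcium`}{(Ca2+-sensitive ligand, e.g. JF646-BAPTA): flickering
#'     precludes time-based filtering, so after the PSF-width filter the
#'     single-frame detections with integrated intensity of at least
#'     `intensity_threshold_cu` camera units (default 261 c.u., the
#'     control-derived active-punctum threshold) are retained.}
#' }
#'
#' @param locs localization data.frame.
#' @param mode `"static_label"` or `"calcium"`.
#' @param pixel_size_um pixel size of the movie, um.
#' @param gain_pe_per_cu camera gain used to express photon intensities in
#'   camera units for the calcium threshold.
#' @param config a [pipeline_config()] supplying the thresholds.
#' @return `static_label`: data.frame `track_id`, `x_nm`, `y_nm`, `n_frames`
#'   (mean positions of retained tracks); `calcium`: the filtered
#'   localization data.frame.
#' @export
filter_mnr_detections <- function(locs, mode = c("static_label", "calcium"),
                                  pixel_size_um, gain_pe_per_cu = 0.229,
                                  config = pipeline_config()) {
  mode <- match.arg(mode)
  locs <- sigma_filter(locs, config$sigma_max_nm)
  if (mode == "calcium") {
    intensity_cu <- locs$intensity_photons / gain_pe_per_cu
    keep <- intensity_cu >= config$intensity_threshold_cu
    pt_log("calcium filter: kept %d of %d detections (>= %g c.u.)",
           sum(keep), nrow(locs), config$intensity_threshold_cu)
    return(locs[keep, , drop = FALSE])
  }
  trajs <- link_trajectories(locs,
                             link_params(radius_px = config$link_radius_px,
                                         gap_frames = 1, min_links = 1),
                             pixel_size_um = pixel_size_um)
  trajs <- persistence_filter(trajs, min_frames = 4)
  det <- trajs[!trajs$interpolated, , drop = FALSE]
  if (!nrow(det))
    return(data.frame(track_id = integer(), x_nm = numeric(), y_nm = numeric(),
                      n_frames = integer()))
  agg <- do.call(rbind, lapply(split_tracks(det), function(tr)
    data.frame(track_id = tr$track_id[1], x_nm = mean(tr$x_nm),
               y_nm = mean(tr$y_nm), n_frames = nrow(tr))))
  rownames(agg) <- NULL
  agg
}

#' Distances from puncta positions to lumen and outer-edge masks
#'
#' The Euclidean distance transform of each mask complement gives, at every
#' pixel, the distance to the nearest mask pixel; positions on mask pixels get
#' distance zero. Pixel-unit distances are rounded *up* to the next integer
#' pixel before conversion to micrometres.
#'
#' @param positions data.frame with `x_nm`, `y_nm` (and optionally an id
#'   column, preserved).
#' @param lumen_mask,outer_mask logical matrices on the movie pixel grid.
#' @param pixel_size_um pixel size, um.
#' @return data.frame `x_nm`, `y_nm`, `d_lumen_um`, `d_outer_um` (plus any id
#'   columns of `positions`).
#' @export
distances_to_masks <- function(positions, lumen_mask, outer_mask,
                               pixel_size_um) {
  px_nm <- pixel_size_um * 1000
  col <- round(positions$x_nm / px_nm) + 1L
  row <- round(positions$y_nm / px_nm) + 1L
  if (any(col < 1 | col > ncol(lumen_mask) | row < 1 | row > nrow(lumen_mask)))
    stopf("position(s) fall outside the mask grid")
  edt_um <- function(mask) {
    if (!any(mask)) stopf("empty mask: distances are undefined")
    d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)))
    ceiling(as.matrix(d) - 1e-9) * pixel_size_um
  }
  dl <- edt_um(lumen_mask); do <- edt_um(outer_mask)
  out <- positions
  out$d_lumen_um <- dl[cbind(row, col)]
  out$d_outer_um <- do[cbind(row, col)]
  out
}

#' 2-D kernel density of paired mask distances
#'
#' Product-Gaussian kernel density over (distance to lumen, distance to outer
#' edge) pairs with fixed per-axis bandwidths (kernel SDs, default
#' 2.503 / 3.661 um), normalized to integrate to one. Evaluated on a regular
#' grid for plotting and at each data point for density-coloured scatter
#' plots.
#'
#' @param d_lumen,d_outer paired distances, um (>= 2 points).
#' @param bandwidths_um per-axis kernel SDs `c(lumen, outer)`.
#' @param grid_n grid resolution per axis.
#' @return list `x`, `y` (grid axes), `z` (density matrix, x indexing rows),
#'   `point_density` (density at each data point).
#' @export
density_scatter <- function(d_lumen, d_outer,
                            bandwidths_um = c(2.503, 3.661), grid_n = 64) {
  stopifnot(length(d_lumen) == length(d_outer))
  if (length(d_lumen) < 2) stopf("need at least 2 points for a density scatter")
  b1 <- bandwidths_um[1]; b2 <- bandwidths_um[2]
  # product Gaussian kernel with per-axis SD = bandwidth (ksdensity convention)
  dens_at <- function(u, v)
    vapply(seq_along(u), function(i)
      mean(dnorm(u[i], d_lumen, b1) * dnorm(v[i], d_outer, b2)), numeric(1))
  gx <- seq(min(d_lumen) - 3 * b1, max(d_lumen) + 3 * b1, length.out = grid_n)
  gy <- seq(min(d_outer) - 3 * b2, max(d_outer) + 3 * b2, length.out = grid_n)
  z <- outer(gx, gy, function(u, v) dens_at(u, v))
  list(x = gx, y = gy, z = z,
       point_density = dens_at(d_lumen, d_outer))
}

#' Summary of a mask-distance distribution
#'
#' Density-normalized histogram (total area one) with fixed-width bins, the
#' empirical CDF, and the fraction of puncta within `near_radius_um` of the
#' mask; when per-video labels are given the near fraction is reported as
#' mean +/- SEM across videos.
#'
#' @param d_um distances, um (nonempty).
#' @param bin_um histogram bin width (default 2 um).
#' @param near_radius_um near-mask radius (default 5 um).
#' @param video optional per-distance video labels for the SEM.
#' @return list `breaks`, `mids`, `density` (per-um density, area sums to 1),
#'   `ecdf` (function), `near_fraction`, `near_fraction_sem`, `n`.
#' @export
distance_summary <- function(d_um, bin_um = 2, near_radius_um = 5,
                             video = NULL) {
  if (!length(d_um)) stopf("no distances supplied")
  hi <- max(bin_um, ceiling(max(d_um) / bin_um + 1e-9) * bin_um)
  breaks <- seq(0, hi, by = bin_um)
  h <- graphics::hist(d_um, breaks = breaks, plot = FALSE, right = FALSE)
  near <- mean(d_um <= near_radius_um)
  near_sem <- if (!is.null(video)) {
    per <- tapply(d_um <= near_radius_um, video, mean)
    sem(as.numeric(per))
  } else NA_real_
  list(breaks = breaks, mids = h$mids,
       density = h$counts / (length(d_um) * bin_um),
       ecdf = ecdf(d_um),
       near_fraction = near, near_fraction_sem = near_sem, n = length(d_um))
}
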