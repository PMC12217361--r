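#' Pipeline configuration
#'
#' Bundle of the fixed analysis constants used across the pipeline. Defaults
#' are the values used throughout the TIRF / lightsheet puncta analyses:
#' 3-pixel linking radius, minimum of 4 links per track, 90 ms allowable gap
#' time for the Ca2+-sensitive probe, 5 s path-length window, 3 um mobility
#' cutoff, 2 s MSD fit range, 280 nm PSF-width filter, 261 c.u. intensity
#' threshold for active puncta, [2.503, 3.661] um KDE bandwidths for
#' lumen/outer-edge distances, 2 um distance-histogram bins, and a 5 um
#' near-mask radius.
#'
#' @param link_radius_px maximum centroid-centroid linking distance, pixels.
#' @param min_links minimum number of links (segments) per emitted track.
#' @param gap_time_s allowable gap time for the Ca2+ probe, seconds; converted
#'   to frames with [gap_frames_for()]. Non-calcium analyses use a single
#'   frame gap.
#' @param path_window_s window over which the path length is summed, seconds.
#' @param mobility_cutoff_um path-length cutoff separating mobile from
#'   immobile tracks, micrometres.
#' @param msd_fit_max_lag_s maximum lag used in the MSD linear fit, seconds.
#' @param sigma_max_nm maximum fitted PSF sigma retained by [sigma_filter()].
#' @param intensity_threshold_cu minimum integrated intensity (camera units)
#'   for active-punctum detections in the calcium filtering path.
#' @param kde_bandwidth_um length-2 kernel SDs (um) for the lumen / outer-edge
#'   distance density scatter.
#' @param hist_bin_um distance histogram bin width, micrometres.
#' @param near_fraction_radius_um radius defining the "near mask" fraction.
#' @param rng_seed optional integer seed recorded with the configuration.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(link_radius_px = 3,
                            min_links = 4,
                            gap_time_s = 0.09,
                            path_window_s = 5,
                            mobility_cutoff_um = 3,
                            msd_fit_max_lag_s = 2,
                            sigma_max_nm = 280,
                            intensity_threshold_cu = 261,
                            kde_bandwidth_um = c(2.503, 3.661),
                            hist_bin_um = 2,
                            near_fraction_radius_um = 5,
                            rng_seed = NULL) {
  cfg <- list(
    link_radius_px = link_radius_px,
    min_links = min_links,
    gap_time_s = gap_time_s,
    path_window_s = path_window_s,
    mobility_cutoff_um = mobility_cutoff_um,
    msd_fit_max_lag_s = msd_fit_max_lag_s,
    sigma_max_nm = sigma_max_nm,
    intensity_threshold_cu = intensity_threshold_cu,
    kde_bandwidth_um = kde_bandwidth_um,
    hist_bin_um = hist_bin_um,
    near_fraction_radius_um = near_fraction_radius_um,
    rng_seed = rng_seed
  )
  num <- cfg[setdiff(names(cfg), "rng_seed")]
  if (any(unlist(num) <= 0)) stopf("all pipeline_config thresholds must be > 0")
  if (length(kde_bandwidth_um) != 2)
    stopf("kde_bandwidth_um must have two entries (lumen, outer edge)")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any key present in the file overrides the corresponding
#' [pipeline_config()] default; unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  cfg <- do.call(pipeline_config, vals)
  pt_log("config read from %s (%d keys overridden)", path, length(vals))
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Allowable gap frames from gap time and frame rate
#'
#' The linker searches up to this many missed frames ahead before terminating
#' a trajectory: `round(gap_time_s * fps)` with a floor of one frame, so a
#' 90 ms gap allowance yields 9 frames at 100 fps and 1 frame at 10 fps.
#'
#' @param gap_time_s allowable gap time in seconds.
#' @param fps frames per second.
#' @return integer number of gap frames (>= 1).
#' @export
gap_frames_for <- function(gap_time_s, fps) {
  if (gap_time_s <= 0 || fps <= 0) stopf("gap_time_s and fps must be > 0")
  max(1L, as.integer(round(gap_time_s * fps)))
}
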