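# Localization and trajectory tables.
#
# A localization table is a data.frame with one row per fitted punctum:
#   frame               0-based frame index
#   x_nm, y_nm          sub-pixel position (centre of pixel (0,0) = 0 nm)
#   sigma_nm            fitted symmetric Gaussian PSF SD
#   intensity_photons   integrated signal above background, photoelectrons
#   background_photons  fitted per-pixel offset above black level, photoelectrons
#
# On disk the table follows the ThunderSTORM export convention:
#   frame,"x [nm]","y [nm]","sigma [nm]","intensity [photon]","offset [photon]"

loc_file_cols <- c(frame = "frame", x_nm = "x [nm]", y_nm = "y [nm]",
                   sigma_nm = "sigma [nm]",
                   intensity_photons = "intensity [photon]",
                   background_photons = "offset [photon]")

#' Construct a localization table
#'
#' @param frame 0-based frame indices.
#' @param x_nm,y_nm sub-pixel positions in nm.
#' @param sigma_nm fitted PSF Gaussian SD in nm (> 0).
#' @param intensity_photons integrated signal in photoelectrons (>= 0).
#' @param background_photons per-pixel background offset in photoelectrons.
#' @return data.frame with the six localization columns.
#' @export
localization_table <- function(frame = integer(), x_nm = numeric(),
                               y_nm = numeric(), sigma_nm = numeric(),
                               intensity_photons = numeric(),
                               background_photons = numeric()) {
  df <- data.frame(frame = as.integer(frame), x_nm = x_nm, y_nm = y_nm,
                   sigma_nm = sigma_nm, intensity_photons = intensity_photons,
                   background_photons = background_photons)
  if (nrow(df)) {
    if (any(df$sigma_nm <= 0)) stopf("sigma_nm must be > 0")
    if (any(df$intensity_photons < 0)) stopf("intensity_photons must be >= 0")
  }
  df
}

#' Read / write localization tables (ThunderSTORM-style CSV)
#'
#' @param path CSV file with header columns `frame`, `x [nm]`, `y [nm]`,
#'   `sigma [nm]`, `intensity [photon]`, `offset [photon]`.
#' @return `read_localizations`: the localization data.frame (possibly empty);
#'   `write_localizations`: `path`, invisibly.
#' @export
read_localizations <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(loc_file_cols), names(df))
  if (length(missing))
    stopf("localization table %s is missing column '%s'", path, missing[1])
  out <- df[, unname(loc_file_cols)]
  names(out) <- names(loc_file_cols)
  out$frame <- as.integer(out$frame)
  pt_log("read %d localizations from %s", nrow(out), path)
  out
}

#' @rdname read_localizations
#' @param locs localization data.frame as from [localization_table()].
#' @export
write_localizations <- function(locs, path) {
  out <- locs[, names(loc_file_cols)]
  names(out) <- unname(loc_file_cols)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# A trajectory table adds to the localization columns:
#   track_id       integer track label
#   interpolated   TRUE for gap frames whose position was linearly interpolated
traj_file_cols <- c(track_id = "track_id", frame = "frame", x_nm = "x [nm]",
                    y_nm = "y [nm]", interpolated = "interpolated")

#' Read / write trajectory tables
#'
#' CSV dialect: `track_id, frame, x [nm], y [nm], interpolated` with
#' interpolated as 0/1.
#'
#' @param path CSV file.
#' @return `read_trajectories`: data.frame with columns `track_id`, `frame`,
#'   `x_nm`, `y_nm`, `interpolated`; `write_trajectories`: `path`, invisibly.
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(traj_file_cols), names(df))
  if (length(missing))
    stopf("trajectory table %s is missing column '%s'", path, missing[1])
  out <- df[, unname(traj_file_cols)]
  names(out) <- names(traj_file_cols)
  out$frame <- as.integer(out$frame)
  out$interpolated <- as.logical(out$interpolated)
  out
}

#' @rdname read_trajectories
#' @param trajs trajectory data.frame as returned by [link_trajectories()].
#' @export
write_trajectories <- function(trajs, path) {
  out <- trajs[, names(traj_file_cols)]
  out$interpolated <- as.integer(out$interpolated)
  names(out) <- unname(traj_file_cols)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# split a trajectory table into per-track data.frames ordered by frame
split_tracks <- function(trajs) {
  trajs <- trajs[order(trajs$track_id, trajs$frame), ]
  split(trajs, trajs$track_id)
}
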