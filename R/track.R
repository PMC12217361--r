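#' Linking parameters
#'
#' @param radius_px maximum centroid-centroid linking distance between frames,
#'   pixels (default 3, i.e. 324 nm at 0.108 um/px).
#' @param gap_frames number of consecutive missed frames the linker searches
#'   ahead before terminating a trajectory (>= 1; compute from a gap time
#'   with [gap_frames_for()]).
#' @param min_links minimum number of links (segments between detected
#'   localizations) a track needs to be emitted.
#' @return list of class `link_params`.
#' @export
link_params <- function(radius_px = 3, gap_frames = 1, min_links = 4) {
  if (radius_px <= 0) stopf("radius_px must be > 0")
  if (min_links < 1) stopf("min_links must be >= 1")
  if (gap_frames < 1) stopf("gap_frames must be >= 1")
  structure(list(radius_px = radius_px, gap_frames = as.integer(gap_frames),
                 min_links = as.integer(min_links)),
            class = "link_params")
}

#' Link per-frame localizations into trajectories
#'
#' Frame-sequential greedy nearest-neighbour assignment: for each frame,
#' candidate pairs between open tracks and new localizations within
#' `radius_px` are ranked by distance and assigned greedily, each localization
#' to at most one track (ties broken by localization order for determinism).
#' A track missing a detection stays open for up to `gap_frames` further
#' frames; once re-linked, positions in the skipped frames are linearly
#' interpolated and flagged. Unassigned localizations start new tracks. Only
#' tracks with at least `min_links` links are emitted.
#'
#' Every input localization is assigned to exactly one (possibly sub-minimum)
#' track; the full assignment is returned in the `"assignments"` attribute so
#' that counts are conserved.
#'
#' @param locs localization data.frame sorted by frame (it is re-sorted
#'   stably if not).
#' @param params a [link_params()].
#' @param pixel_size_um pixel size used to express the radius in nm.
#' @return Trajectory data.frame with columns `track_id`, `frame`, `x_nm`,
#'   `y_nm`, `interpolated`, `sigma_nm`, `intensity_photons` (NA on
#'   interpolated rows), ordered by track and frame. Attribute `assignments`:
#'   integer track id per input row (in the input's frame-sorted order).
#' @export
link_trajectories <- function(locs, params = link_params(), pixel_size_um) {
  if (missing(pixel_size_um)) stopf("pixel_size_um is required for linking")
  radius_nm <- params$radius_px * pixel_size_um * 1000
  ord <- order(locs$frame)
  locs <- locs[ord, , drop = FALSE]
  n <- nrow(locs)
  assign_id <- integer(n)
  # open tracks: parallel vectors
  tr_last_idx <- integer(0)   # row index of last detection
  tr_last_frame <- integer(0)
  tr_rows <- list()           # detected row indices per track
  next_id <- 0L
  if (n > 0) {
    for (f in sort(unique(locs$frame))) {
      rows_f <- which(locs$frame == f)
      # close tracks whose gap allowance is exhausted
      open <- which(f - tr_last_frame <= params$gap_frames + 1L)
      if (length(open) && length(rows_f)) {
        dx <- outer(locs$x_nm[tr_last_idx[open]], locs$x_nm[rows_f], "-")
        dy <- outer(locs$y_nm[tr_last_idx[open]], locs$y_nm[rows_f], "-")
        dist <- sqrt(dx^2 + dy^2)
        cand <- which(dist <= radius_nm, arr.ind = TRUE)
        if (nrow(cand)) {
          # greedy: closest pair first; ties by localization then track order
          o <- order(dist[cand], cand[, 2], cand[, 1])
          used_tr <- logical(length(open)); used_loc <- logical(length(rows_f))
          for (k in o) {
            ti <- cand[k, 1]; li <- cand[k, 2]
            if (used_tr[ti] || used_loc[li]) next
            used_tr[ti] <- TRUE; used_loc[li] <- TRUE
            tr <- open[ti]; row <- rows_f[li]
            tr_rows[[tr]] <- c(tr_rows[[tr]], row)
            tr_last_idx[tr] <- row
            tr_last_frame[tr] <- f
            assign_id[row] <- tr
          }
          rows_f <- rows_f[!used_loc]
        }
      }
      for (row in rows_f) {   # unassigned localizations start new tracks
        next_id <- next_id + 1L
        tr_rows[[next_id]] <- row
        tr_last_idx[next_id] <- row
        tr_last_frame[next_id] <- f
        assign_id[row] <- next_id
      }
    }
  }
  n_links <- vapply(tr_rows, length, 1L) - 1L
  keep <- which(n_links >= params$min_links)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    rows <- tr_rows[[keep[i]]]
    d <- locs[rows, c("frame", "x_nm", "y_nm", "sigma_nm",
                      "intensity_photons")]
    d$interpolated <- FALSE
    frames_full <- min(d$frame):max(d$frame)
    gaps <- setdiff(frames_full, d$frame)
    if (length(gaps)) {
      gi <- data.frame(frame = gaps,
                       x_nm = stats::approx(d$frame, d$x_nm, xout = gaps)$y,
                       y_nm = stats::approx(d$frame, d$y_nm, xout = gaps)$y,
                       sigma_nm = NA_real_, intensity_photons = NA_real_,
                       interpolated = TRUE)
      d <- rbind(d, gi)
    }
    d <- d[order(d$frame), ]
    d <- cbind(track_id = i, d)
    out[[i]] <- d
  }
  trajs <- if (length(out)) do.call(rbind, out) else
    data.frame(track_id = integer(), frame = integer(), x_nm = numeric(),
               y_nm = numeric(), sigma_nm = numeric(),
               intensity_photons = numeric(), interpolated = logical())
  rownames(trajs) <- NULL
  trajs <- trajs[, c("track_id", "frame", "x_nm", "y_nm", "interpolated",
                     "sigma_nm", "intensity_photons")]
  pt_log("linked %d localizations into %d tracks (%d above %d links)",
         n, next_id, length(keep), params$min_links)
  attr(trajs, "assignments") <- assign_id
  trajs
}

#' Persistence filter: keep tracks detected in enough frames
#'
#' Retains tracks detected (not interpolated) in at least `min_frames` frames;
#' single-frame spurious detections and other short-lived objects are removed.
#' The default matches the rule that bona fide puncta tracks comprise at least
#' 3 linked segments, i.e. detections in at least 4 frames.
#'
#' @param trajs trajectory data.frame from [link_trajectories()].
#' @param min_frames minimum number of detected frames.
#' @return The filtered trajectory data.frame.
#' @export
persistence_filter <- function(trajs, min_frames = 4) {
  if (!nrow(trajs)) return(trajs)
  det <- tapply(!trajs$interpolated, trajs$track_id, sum)
  keep_ids <- as.integer(names(det)[det >= min_frames])
  out <- trajs[trajs$track_id %in% keep_ids, , drop = FALSE]
  pt_log("persistence filter: kept %d of %d tracks (>= %d detected frames)",
         length(keep_ids), length(det), min_frames)
  out
}
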