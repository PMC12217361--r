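#' Movie stack container
#'
#' A grayscale microscopy movie in raw camera units together with the metadata
#' needed to convert to physical units: pixel size, frame interval, camera
#' gain (photoelectrons per camera unit) and camera black level.
#'
#' Coordinate convention: frames, rows and columns are 0-based in all reported
#' positions; the centre of pixel (row 0, col 0) is position (0 nm, 0 nm) and
#' x runs along the column axis.
#'
#' @param data numeric array `frame x row x col`, or a single matrix which is
#'   promoted to a 1-frame stack. Camera units, non-negative.
#' @param pixel_size_um pixel size in micrometres (e.g. 0.108).
#' @param frame_interval_s frame interval in seconds.
#' @param gain_pe_per_cu photoelectrons per camera unit (e.g. 0.229).
#' @param black_level_cu camera offset in camera units.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, pixel_size_um, frame_interval_s,
                        gain_pe_per_cu = 0.229, black_level_cu = 0) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (length(dim(data)) != 3L) stopf("movie data must be a frame x row x col array")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be > 0")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stopf("frame_interval_s must be > 0")
  if (gain_pe_per_cu <= 0) stopf("gain_pe_per_cu must be > 0")
  if (min(data) < 0) stopf("camera-unit data must be non-negative")
  structure(list(data = data,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 gain_pe_per_cu = gain_pe_per_cu,
                 black_level_cu = black_level_cu),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<movie_stack> %d frames of %d x %d px | %.4g um/px | ",
                     "%.4g s/frame | gain %.4g pe/c.u. | black %.4g c.u.\n"),
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s,
              x$gain_pe_per_cu, x$black_level_cu))
  invisible(x)
}

#' @rdname movie_stack
#' @param movie a `movie_stack`.
#' @export
n_frames <- function(movie) dim(movie$data)[1]

#' @rdname movie_stack
#' @param i 0-based frame index.
#' @export
get_frame <- function(movie, i) movie$data[i + 1L, , ]

metadata_keys <- c("pixel_size_um", "frame_interval_s",
                   "gain_pe_per_cu", "black_level_cu")

sidecar_path <- function(path) paste0(path, ".yaml")

#' Read a movie from a multi-page TIFF
#'
#' Pixel data are read as raw integer camera units. Metadata (pixel size,
#' frame interval, gain, black level) are taken from the arguments, or from a
#' YAML sidecar file `<path>.yaml` written by [write_movie()]; arguments win.
#' A missing pixel size or frame interval is a configuration error, never a
#' silent default.
#'
#' @param path TIFF file (single- or multi-page; a single page becomes a
#'   1-frame stack).
#' @param pixel_size_um,frame_interval_s,gain_pe_per_cu,black_level_cu
#'   metadata overrides; see [movie_stack()].
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       gain_pe_per_cu = NULL, black_level_cu = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list()
  if (file.exists(sidecar_path(path))) meta <- yaml::read_yaml(sidecar_path(path))
  meta$pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  meta$frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
  meta$gain_pe_per_cu <- gain_pe_per_cu %||% meta$gain_pe_per_cu %||% 0.229
  meta$black_level_cu <- black_level_cu %||% meta$black_level_cu %||% 0
  for (k in c("pixel_size_um", "frame_interval_s")) {
    if (is.null(meta[[k]]))
      stopf("configuration error: '%s' missing for %s (supply it or a %s sidecar)",
            k, path, sidecar_path(basename(path)))
  }
  data <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) data[i, , ] <- pages[[i]]
  pt_log("read %d frames from %s", length(pages), path)
  movie_stack(data, meta$pixel_size_um, meta$frame_interval_s,
              meta$gain_pe_per_cu, meta$black_level_cu)
}

#' Write a movie to a 16-bit TIFF with a metadata sidecar
#'
#' Camera units must be integers in [0, 65535]; the write-then-read round trip
#' is then bit exact. Metadata go into a YAML sidecar next to the TIFF.
#'
#' @param movie a [movie_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- movie$data
  if (max(abs(d - round(d))) > 1e-9)
    stopf("movie data must be integer camera units for 16-bit TIFF output")
  if (max(d) > 65535) stopf("camera units exceed the 16-bit range")
  pages <- lapply(seq_len(dim(d)[1]), function(i) d[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(movie[metadata_keys], sidecar_path(path))
  invisible(path)
}

#' Read a binary mask image
#'
#' 8-bit TIFF or PNG; any nonzero pixel is part of the mask. When `movie` is
#' supplied the mask must share its pixel grid.
#'
#' @param path image file (.tif/.tiff/.png).
#' @param movie optional [movie_stack()] whose frame shape the mask must match.
#' @return A logical matrix.
#' @export
read_mask <- function(path, movie = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path),
    stopf("unsupported mask format '%s'", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel
  mask <- img != 0
  if (!is.null(movie)) {
    fd <- dim(movie$data)[2:3]
    if (!all(dim(mask) == fd))
      stopf("mask shape %d x %d does not match movie frames %d x %d",
            nrow(mask), ncol(mask), fd[1], fd[2])
  }
  mask
}

#' Write a binary mask as an 8-bit image
#'
#' @param mask logical (or 0/1) matrix.
#' @param path output path (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    stopf("unsupported mask format '%s'", ext))
  invisible(path)
}
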