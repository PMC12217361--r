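# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard error of the mean
#'
#' @param x numeric vector; NAs removed.
#' @return `sd(x)/sqrt(n)`.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Stage logging: emitted via message() when options(punctatrack.verbose = TRUE).
pt_log <- function(fmt, ...) {
  if (isTRUE(getOption("punctatrack.verbose", FALSE))) {
    message(sprintf(paste0("[punctatrack] ", fmt), ...))
  }
  invisible(NULL)
}

# Run code with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. Guarantees bit-reproducibility of seeded generators
# without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Integrated 1-D Gaussian flux over unit pixels centred at integer coordinates
# `centers` (pixel units), for an emitter at `mu` with SD `sigma`.
pixel_gauss <- function(centers, mu, sigma) {
  pnorm(centers + 0.5, mean = mu, sd = sigma) -
    pnorm(centers - 0.5, mean = mu, sd = sigma)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
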