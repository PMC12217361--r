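#' Simulation specification
#'
#' Parameters of the synthetic TIRF movie generator. The defaults describe a
#' typical endothelial-cell field imaged at 10 fps: a mix of immobile puncta
#' and mobile puncta diffusing at 0.029 um^2/s, a 189 nm PSF, 29 nm per-axis
#' localization noise on reported positions, ~950 photoelectrons per punctum
#' per frame (the c.u. equivalent of the brightest HaloTag-ligand puncta) and
#' a 38.1 s photobleaching time constant. Flicker kinetics are illustrative
#' only: no kinetic rates are established for PIEZO1 flickers, so `k_open` and
#' `k_close` defaults are order-of-magnitude placeholders to be set by the
#' user.
#'
#' @param n_immobile,n_mobile punctum counts per population.
#' @param D_um2_s diffusion coefficient of the mobile population, um^2/s.
#' @param anomalous_alpha MSD exponent; 1 = Brownian, < 1 = sub-Brownian
#'   fractional Brownian motion.
#' @param loc_noise_nm per-axis Gaussian noise added to every *reported*
#'   position (localization error); true positions are kept separately.
#' @param psf_sigma_nm PSF Gaussian SD used for rendering.
#' @param photons_per_punctum expected photoelectrons emitted per punctum per
#'   frame at full brightness (per channel for flicker traces).
#' @param bleach_tau_s photobleaching time constant applied to emission
#'   amplitude.
#' @param background_photons per-pixel background, photoelectrons per frame.
#' @param k_open,k_close two-state gating rates, 1/s (closed->open,
#'   open->closed).
#' @param dim_fraction relative brightness of the closed/dim state in [0, 1];
#'   0 makes a closed punctum indistinguishable from background.
#' @param cluster_size number of independent channels per punctum.
#' @param n_frames,fps movie length and frame rate.
#' @param image_size_px square frame edge, pixels.
#' @param pixel_size_um,gain_pe_per_cu,black_level_cu camera geometry; see
#'   [movie_stack()].
#' @param shot_noise apply Poisson photon noise when rendering.
#' @param quantize round rendered frames to integer camera units.
#' @param seed default RNG seed used when a generator is called without one.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_immobile = 20, n_mobile = 20,
                            D_um2_s = 0.029, anomalous_alpha = 1,
                            loc_noise_nm = 29, psf_sigma_nm = 189,
                            photons_per_punctum = 950, bleach_tau_s = 38.1,
                            background_photons = 10,
                            k_open = 0.5, k_close = 5, dim_fraction = 0,
                            cluster_size = 1,
                            n_frames = 50, fps = 10, image_size_px = 64,
                            pixel_size_um = 0.108, gain_pe_per_cu = 0.229,
                            black_level_cu = 100,
                            shot_noise = TRUE, quantize = TRUE, seed = NULL) {
  spec <- as.list(environment())
  if (spec$D_um2_s < 0 || spec$k_open < 0 || spec$k_close < 0)
    stopf("rates and diffusion coefficients must be >= 0")
  if (spec$dim_fraction < 0 || spec$dim_fraction > 1)
    stopf("dim_fraction must lie in [0, 1]")
  if (spec$anomalous_alpha <= 0 || spec$anomalous_alpha > 2)
    stopf("anomalous_alpha must lie in (0, 2]")
  structure(spec, class = "simulation_spec")
}

# Per-axis fractional Brownian motion at times t = (1:n)*dt with
# E[x(t)^2] = 2*D*t^alpha. alpha = 1 reduces to cumulative Gaussian steps.
fbm_axis <- function(n, D, dt, alpha) {
  if (n == 0) return(numeric(0))
  if (D == 0) return(numeric(n))
  if (alpha == 1) return(cumsum(rnorm(n, sd = sqrt(2 * D * dt))))
  t <- (1:n) * dt
  cov <- D * (outer(t, t, function(s, u) s^alpha + u^alpha - abs(s - u)^alpha))
  L <- chol(cov + diag(1e-12, n))
  as.vector(t(L) %*% rnorm(n))
}

#' Simulate ground-truth punctum trajectories
#'
#' Mobile puncta follow 2-D (fractional) Brownian motion with per-axis step
#' variance `2 * D * dt^alpha`; immobile puncta are static. Independent
#' per-axis Gaussian noise of SD `loc_noise_nm` is added to every *reported*
#' position, emulating localization error; true positions are returned
#' unperturbed.
#'
#' @param spec a [simulation_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return data.frame ground truth with one row per punctum per frame:
#'   `id`, `label` ("immobile"/"mobile"), `frame`, `t_s`, true `x_um`/`y_um`
#'   and reported `x_obs_um`/`y_obs_um`.
#' @export
simulate_trajectories <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    n <- spec$n_immobile + spec$n_mobile
    if (n == 0) return(empty_truth())
    dt <- 1 / spec$fps
    fov_um <- spec$image_size_px * spec$pixel_size_um
    margin <- 6 * spec$psf_sigma_nm / 1000
    labels <- rep(c("immobile", "mobile"), c(spec$n_immobile, spec$n_mobile))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      x0 <- runif(1, margin, fov_um - margin)
      y0 <- runif(1, margin, fov_um - margin)
      if (labels[i] == "mobile") {
        dxy <- cbind(c(0, fbm_axis(spec$n_frames - 1, spec$D_um2_s, dt,
                                   spec$anomalous_alpha)),
                     c(0, fbm_axis(spec$n_frames - 1, spec$D_um2_s, dt,
                                   spec$anomalous_alpha)))
      } else {
        dxy <- matrix(0, spec$n_frames, 2)
      }
      s <- spec$loc_noise_nm / 1000
      noise <- matrix(rnorm(2 * spec$n_frames, sd = s), ncol = 2)
      out[[i]] <- data.frame(
        id = i, label = labels[i], frame = 0:(spec$n_frames - 1),
        t_s = (0:(spec$n_frames - 1)) * dt,
        x_um = x0 + dxy[, 1], y_um = y0 + dxy[, 2],
        x_obs_um = x0 + dxy[, 1] + noise[, 1],
        y_obs_um = y0 + dxy[, 2] + noise[, 2])
    }
    truth <- do.call(rbind, out)
    pt_log("simulated %d puncta (%d immobile, %d mobile) x %d frames",
           n, spec$n_immobile, spec$n_mobile, spec$n_frames)
    truth
  })
}

#' Convert ground truth to a trajectory table
#'
#' Turns the per-frame ground truth of [simulate_trajectories()] into the
#' trajectory format used by the mobility and activity stages, bypassing
#' detection and linking (ideal-tracking analyses).
#'
#' @param truth data.frame from [simulate_trajectories()].
#' @param observed use reported (noisy) positions; `FALSE` uses true positions.
#' @return trajectory data.frame (`track_id`, `frame`, `x_nm`, `y_nm`,
#'   `interpolated`).
#' @export
truth_to_trajectories <- function(truth, observed = TRUE) {
  data.frame(track_id = truth$id, frame = truth$frame,
             x_nm = (if (observed) truth$x_obs_um else truth$x_um) * 1000,
             y_nm = (if (observed) truth$y_obs_um else truth$y_um) * 1000,
             interpolated = FALSE)
}

empty_truth <- function() {
  data.frame(id = integer(), label = character(), frame = integer(),
             t_s = numeric(), x_um = numeric(), y_um = numeric(),
             x_obs_um = numeric(), y_obs_um = numeric())
}

#' Simulate a two-state flicker intensity trace
#'
#' Each of the `cluster_size` channels in a punctum is an independent two-state
#' Markov chain with opening rate `k_open` and closing rate `k_close`
#' (initialized at the stationary distribution). Punctum brightness per frame
#' is `(n_open + dim_fraction * n_closed) * photons_per_punctum`, so the
#' long-run open occupancy tends to `k_open / (k_open + k_close)`.
#'
#' @param spec a [simulation_spec()].
#' @param n_frames trace length in frames.
#' @param seed RNG seed.
#' @return data.frame with `frame`, `t_s`, `n_open` and `photons`.
#' @export
simulate_flicker_trace <- function(spec, n_frames = spec$n_frames,
                                   seed = spec$seed) {
  with_seed(seed, {
    dt <- 1 / spec$fps
    ko <- spec$k_open; kc <- spec$k_close
    ktot <- ko + kc
    p_open_stat <- if (ktot > 0) ko / ktot else 0
    # exact discrete-time transition probabilities of the two-state chain
    decay <- if (ktot > 0) exp(-ktot * dt) else 1
    p_co <- p_open_stat * (1 - decay)          # closed -> open over dt
    p_oc <- (1 - p_open_stat) * (1 - decay)    # open -> closed over dt
    n_open <- integer(n_frames)
    for (ch in seq_len(spec$cluster_size)) {
      open <- runif(1) < p_open_stat
      for (f in seq_len(n_frames)) {
        if (f > 1) {
          u <- runif(1)
          open <- if (open) u >= p_oc else u < p_co
        }
        n_open[f] <- n_open[f] + open
      }
    }
    n_closed <- spec$cluster_size - n_open
    data.frame(frame = 0:(n_frames - 1), t_s = (0:(n_frames - 1)) * dt,
               n_open = n_open,
               photons = (n_open + spec$dim_fraction * n_closed) *
                 spec$photons_per_punctum)
  })
}

# Add one punctum's photons to a photon image. Integrated (not point-sampled)
# Gaussian PSF: flux over each pixel is the product of erf differences, which
# keeps sub-pixel recovery unbiased. Returns TRUE if any flux was clipped.
add_punctum <- function(img, x_px, y_px, photons, sigma_px) {
  nr <- nrow(img); nc <- ncol(img)
  half <- ceiling(7 * sigma_px)
  cols <- max(0, floor(x_px - half)):min(nc - 1, ceiling(x_px + half))
  rows <- max(0, floor(y_px - half)):min(nr - 1, ceiling(y_px + half))
  clipped <- x_px < -0.5 || x_px > nc - 0.5 || y_px < -0.5 || y_px > nr - 0.5
  if (!length(cols) || !length(rows)) return(list(img = img, clipped = TRUE))
  fx <- pixel_gauss(cols, x_px, sigma_px)
  fy <- pixel_gauss(rows, y_px, sigma_px)
  img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
    photons * (fy %o% fx)
  list(img = img, clipped = clipped)
}

#' Render a synthetic movie from ground truth
#'
#' Each punctum is rendered as an integrated 2-D Gaussian of SD
#' `psf_sigma_nm`, at its *true* position, with per-frame photon budget
#' `photons_per_punctum * exp(-t / bleach_tau_s)` (or the `photons` column of
#' `truth` when present, e.g. from [simulate_flicker_trace()], which is then
#' also bleached). Per-pixel background photons are added, Poisson shot noise
#' applied when `spec$shot_noise`, and the image converted to camera units via
#' the gain and black level, rounded to integers when `spec$quantize`.
#'
#' @param truth ground-truth data.frame from [simulate_trajectories()];
#'   an optional `photons` column overrides the constant photon budget.
#' @param spec a [simulation_spec()].
#' @param seed RNG seed for the shot noise.
#' @return A [movie_stack()].
#' @export
render_movie <- function(truth, spec, seed = spec$seed) {
  with_seed(seed, {
    npx <- spec$image_size_px
    sigma_px <- spec$psf_sigma_nm / 1000 / spec$pixel_size_um
    dt <- 1 / spec$fps
    data <- array(0, dim = c(spec$n_frames, npx, npx))
    n_clipped <- 0L
    for (f in 0:(spec$n_frames - 1)) {
      img <- matrix(spec$background_photons, npx, npx)
      rows <- truth[truth$frame == f, , drop = FALSE]
      bleach <- exp(-f * dt / spec$bleach_tau_s)
      if (nrow(rows)) {
        for (j in seq_len(nrow(rows))) {
          photons <- if ("photons" %in% names(rows)) rows$photons[j]
                     else spec$photons_per_punctum
          res <- add_punctum(img,
                             rows$x_um[j] / spec$pixel_size_um,
                             rows$y_um[j] / spec$pixel_size_um,
                             photons * bleach, sigma_px)
          img <- res$img
          n_clipped <- n_clipped + res$clipped
        }
      }
      if (spec$shot_noise) img <- matrix(rpois(npx * npx, img), npx, npx)
      cu <- img / spec$gain_pe_per_cu + spec$black_level_cu
      if (spec$quantize) cu <- pmin(round(cu), 65535)
      data[f + 1L, , ] <- cu
    }
    if (n_clipped > 0)
      warnf("%d punctum renderings extended beyond the frame and were clipped",
            n_clipped)
    movie_stack(data, spec$pixel_size_um, dt,
                spec$gain_pe_per_cu, spec$black_level_cu)
  })
}

#' Organoid (neural-rosette) scene specification
#'
#' Desk-scale model of a micropatterned neural rosette: cells arranged
#' radially around a central lumen, imaged as a maximum-intensity-projection
#' time series. True puncta are static emitters placed in the tissue annulus
#' between the lumen border and the outer edge, optionally enriched towards
#' the lumen. Contaminants emulate the two spurious-signal classes seen in
#' real organoids: large autofluorescent blobs (PSF SD well above the 280 nm
#' filter) persisting through the movie, and single-frame spurious spots
#' (unbound dye / background fluctuations) that cannot form multi-frame
#' tracks.
#'
#' @param n_puncta true punctum count.
#' @param lumen_radius_um,outer_radius_um annulus geometry (lumen < outer).
#' @param edge_width_px width of the outer-edge mask ring, pixels.
#' @param lumen_enrichment fraction of true puncta drawn from an
#'   exponential-decay profile against distance to the lumen border
#'   (0 = uniform over the annulus).
#' @param enrichment_scale_um decay length of the enrichment profile.
#' @param n_blobs,blob_sigma_nm autofluorescent blob count and size.
#' @param blob_photons photon budget of a blob per frame.
#' @param n_spurious single-frame spurious spot count (one random frame each).
#' @param n_frames,frame_interval_s movie geometry (defaults mirror a 30-point
#'   MIP series over ~5.5 s).
#' @param image_size_px,pixel_size_um,gain_pe_per_cu,black_level_cu camera
#'   geometry.
#' @param psf_sigma_nm,photons_per_punctum,background_photons rendering
#'   parameters for true puncta.
#' @param seed default RNG seed.
#' @return list of class `mnr_spec`.
#' @export
mnr_spec <- function(n_puncta = 30, lumen_radius_um = 4, outer_radius_um = 9,
                     edge_width_px = 3, lumen_enrichment = 0,
                     enrichment_scale_um = 2,
                     n_blobs = 5, blob_sigma_nm = 450, blob_photons = 4000,
                     n_spurious = 8,
                     n_frames = 30, frame_interval_s = 0.18,
                     image_size_px = 192, pixel_size_um = 0.108,
                     gain_pe_per_cu = 0.229, black_level_cu = 100,
                     psf_sigma_nm = 189, photons_per_punctum = 950,
                     background_photons = 10, seed = NULL) {
  spec <- as.list(environment())
  if (spec$lumen_radius_um >= spec$outer_radius_um)
    stopf("lumen radius must be smaller than the outer radius")
  if (spec$outer_radius_um >
      spec$image_size_px * spec$pixel_size_um / 2 - 1)
    stopf("outer radius does not fit in the field of view")
  structure(spec, class = "mnr_spec")
}

#' Simulate an organoid scene with masks and ground truth
#'
#' @param spec an [mnr_spec()].
#' @param seed RNG seed.
#' @return list of class `mnr_scene` with elements `movie` ([movie_stack()]),
#'   `lumen_mask`, `outer_mask` (logical matrices), and `truth`: one row per
#'   object with `id`, `type` ("punctum"/"blob"/"spurious"), position, size and
#'   the frame span it appears in.
#' @export
simulate_mnr_scene <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    npx <- spec$image_size_px
    px <- spec$pixel_size_um
    centre <- (npx - 1) / 2 * px
    # radial pixel distances from the scene centre (pixel centres, um)
    ax <- (0:(npx - 1)) * px - centre
    rr <- sqrt(outer(ax^2, ax^2, "+"))  # [row, col] with y = rows
    lumen_mask <- rr <= spec$lumen_radius_um
    outer_mask <- rr >= spec$outer_radius_um &
      rr <= spec$outer_radius_um + spec$edge_width_px * px
    draw_annulus <- function(n) {
      # uniform over the tissue annulus by rejection
      out <- matrix(numeric(0), 0, 2)
      while (nrow(out) < n) {
        m <- 4 * (n - nrow(out)) + 16
        x <- runif(m, -spec$outer_radius_um, spec$outer_radius_um)
        y <- runif(m, -spec$outer_radius_um, spec$outer_radius_um)
        r <- sqrt(x^2 + y^2)
        keep <- r > spec$lumen_radius_um & r < spec$outer_radius_um
        out <- rbind(out, cbind(x[keep], y[keep]))
      }
      out[seq_len(n), , drop = FALSE] + centre
    }
    draw_enriched <- function(n) {
      # exponential decay of distance beyond the lumen border
      d <- rexp(n, rate = 1 / spec$enrichment_scale_um)
      d <- pmin(d, spec$outer_radius_um - spec$lumen_radius_um - 1e-6)
      r <- spec$lumen_radius_um + d
      th <- runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th)) + centre
    }
    n_enr <- if (spec$n_puncta > 0)
      sum(runif(spec$n_puncta) < spec$lumen_enrichment) else 0L
    pos <- rbind(draw_enriched(n_enr), draw_annulus(spec$n_puncta - n_enr))
    truth <- list()
    if (spec$n_puncta > 0)
      truth$puncta <- data.frame(
        type = "punctum", x_um = pos[, 1], y_um = pos[, 2],
        sigma_nm = spec$psf_sigma_nm, photons = spec$photons_per_punctum,
        first_frame = 0L, last_frame = spec$n_frames - 1L)
    if (spec$n_blobs > 0) {
      bp <- draw_annulus(spec$n_blobs)
      truth$blobs <- data.frame(
        type = "blob", x_um = bp[, 1], y_um = bp[, 2],
        sigma_nm = spec$blob_sigma_nm, photons = spec$blob_photons,
        first_frame = 0L, last_frame = spec$n_frames - 1L)
    }
    if (spec$n_spurious > 0) {
      sp <- draw_annulus(spec$n_spurious)
      truth$spurious <- data.frame(
        type = "spurious", x_um = sp[, 1], y_um = sp[, 2],
        sigma_nm = spec$psf_sigma_nm, photons = spec$photons_per_punctum,
        first_frame = sample(0:(spec$n_frames - 1L), spec$n_spurious,
                             replace = TRUE))
      truth$spurious$last_frame <- truth$spurious$first_frame
    }
    truth <- do.call(rbind, truth)
    truth$id <- seq_len(nrow(truth))
    rownames(truth) <- NULL
    data <- array(0, dim = c(spec$n_frames, npx, npx))
    for (f in 0:(spec$n_frames - 1)) {
      img <- matrix(spec$background_photons, npx, npx)
      on_frame <- truth[truth$first_frame <= f & truth$last_frame >= f, ]
      for (j in seq_len(nrow(on_frame))) {
        img <- add_punctum(img,
                           on_frame$x_um[j] / px, on_frame$y_um[j] / px,
                           on_frame$photons[j],
                           on_frame$sigma_nm[j] / 1000 / px)$img
      }
      img <- matrix(rpois(npx * npx, img), npx, npx)
      data[f + 1L, , ] <- pmin(round(img / spec$gain_pe_per_cu +
                                       spec$black_level_cu), 65535)
    }
    movie <- movie_stack(data, px, spec$frame_interval_s,
                         spec$gain_pe_per_cu, spec$black_level_cu)
    pt_log("MNR scene: %d puncta, %d blobs, %d spurious spots",
           spec$n_puncta, spec$n_blobs, spec$n_spurious)
    structure(list(movie = movie, lumen_mask = lumen_mask,
                   outer_mask = outer_mask, truth = truth, spec = spec),
              class = "mnr_scene")
  })
}
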