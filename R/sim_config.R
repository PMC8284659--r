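#' Simulation configuration
#'
#' Bundles the physical and acquisition parameters of the synthetic
#' fluorescence generator. Defaults emulate spinning-disk imaging of
#' cultured neurons expressing an EB plus-end marker: 1 s frames for 1 min,
#' ~0.1 um pixels, comets of ~1 um with velocities of a few tenths of a
#' um/s.
#'
#' `comet_amplitude` is the integrated linear intensity density of a comet
#' (flux per unit length at the tip, before optical blurring). The total
#' flux of a rendered comet is therefore independent of `psf_sigma_um`;
#' its peak pixel value is not. Use [amplitude_for_snr()] to pick an
#' amplitude producing a desired peak signal-to-noise ratio.
#'
#' @param pixel_size_um um per pixel (> 0).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param n_frames number of frames in a movie (>= 2).
#' @param image_shape integer vector `c(rows, cols)`.
#' @param axon_length_um axon arclength in um (20-150 um typical).
#' @param comet_velocity_um_s signed comet velocity; positive =
#'   anterograde (away from the soma end of the trace).
#' @param comet_nucleation_rate_per_um_min nucleation events per um of
#'   axon per minute.
#' @param comet_lifetime_mean_s mean of the exponential comet lifetime.
#' @param comet_tail_length_um decay length of the exponential comet tail.
#' @param comet_amplitude integrated linear intensity density in
#'   intensity x um units (see above).
#' @param lattice_intensity approximate on-axis intensity of the
#'   microtubule-lattice signal painted along the trace.
#' @param bg_offset constant camera offset added to every pixel.
#' @param gaussian_noise_sd sd of additive Gaussian read noise (0 = off).
#' @param poisson_noise logical; apply Poisson shot noise to the noiseless
#'   image (offset included) before the Gaussian component.
#' @param psf_sigma_um Gaussian PSF sigma in um.
#' @param rng_seed integer seed making the simulation reproducible, or
#'   `NULL` to draw from the session RNG.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(pixel_size_um = 0.1,
                       frame_interval_s = 1,
                       n_frames = 60,
                       image_shape = c(96, 560),
                       axon_length_um = 50,
                       comet_velocity_um_s = 0.2,
                       comet_nucleation_rate_per_um_min = 0.5,
                       comet_lifetime_mean_s = 20,
                       comet_tail_length_um = 1,
                       comet_amplitude = 10,
                       lattice_intensity = 5,
                       bg_offset = 100,
                       gaussian_noise_sd = 0,
                       poisson_noise = FALSE,
                       psf_sigma_um = 0.15,
                       rng_seed = NULL) {
  cfg <- list(pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              n_frames = as.integer(n_frames),
              image_shape = as.integer(image_shape),
              axon_length_um = axon_length_um,
              comet_velocity_um_s = comet_velocity_um_s,
              comet_nucleation_rate_per_um_min = comet_nucleation_rate_per_um_min,
              comet_lifetime_mean_s = comet_lifetime_mean_s,
              comet_tail_length_um = comet_tail_length_um,
              comet_amplitude = comet_amplitude,
              lattice_intensity = lattice_intensity,
              bg_offset = bg_offset,
              gaussian_noise_sd = gaussian_noise_sd,
              poisson_noise = isTRUE(poisson_noise),
              psf_sigma_um = psf_sigma_um,
              rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos <- c("pixel_size_um", "frame_interval_s", "axon_length_um",
           "comet_nucleation_rate_per_um_min", "comet_lifetime_mean_s",
           "comet_tail_length_um", "comet_amplitude", "psf_sigma_um")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("sim_config: '", f, "' must be a positive scalar")
  nneg <- c("lattice_intensity", "bg_offset", "gaussian_noise_sd")
  for (f in nneg)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop("sim_config: '", f, "' must be a non-negative scalar")
  if (!is.numeric(cfg$comet_velocity_um_s) || length(cfg$comet_velocity_um_s) != 1L)
    stop("sim_config: 'comet_velocity_um_s' must be a scalar (signed)")
  if (cfg$n_frames < 2L) stop("sim_config: n_frames must be >= 2")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 8L))
    stop("sim_config: image_shape must be c(rows, cols), each >= 8")
  ## image must hold the trace with a >= 5 px margin
  need_px <- cfg$axon_length_um / cfg$pixel_size_um + 10
  if (cfg$image_shape[2] < need_px)
    stop(sprintf(paste0("sim_config: image too small for a %g um axon at ",
                        "%g um/px (need >= %d columns with a 5 px margin)"),
                 cfg$axon_length_um, cfg$pixel_size_um, ceiling(need_px)))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d frames @ %g s, %d x %d px @ %g um/px\n",
                     "  axon %g um, v = %g um/s, rate %g /um/min, ",
                     "lifetime %g s, tail %g um\n"),
              x$n_frames, x$frame_interval_s, x$image_shape[1],
              x$image_shape[2], x$pixel_size_um, x$axon_length_um,
              x$comet_velocity_um_s, x$comet_nucleation_rate_per_um_min,
              x$comet_lifetime_mean_s, x$comet_tail_length_um))
  invisible(x)
}
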