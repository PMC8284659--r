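## Still-image comet quantification: background estimation, comet
## detection along a trace, per-comet length / mean intensity / amount,
## and lattice (shaft) intensity.

#' Estimate the fluorescence background
#'
#' Median intensity outside comet exclusion zones. At least 25% of the
#' samples must lie outside the zones.
#'
#' @param x an `intensity_profile` or an [image2d()].
#' @param ... passed to methods.
#' @return Scalar background estimate.
#' @export
estimate_background <- function(x, ...) UseMethod("estimate_background")

#' @rdname estimate_background
#' @param comet_positions_um arclength positions (um) to exclude.
#' @param exclusion_radius_um half-width of each exclusion zone (um).
#' @export
estimate_background.intensity_profile <- function(x, comet_positions_um = NULL,
                                                  exclusion_radius_um = 1, ...) {
  keep <- rep(TRUE, length(x$arclength_um))
  for (p in comet_positions_um)
    keep <- keep & abs(x$arclength_um - p) > exclusion_radius_um
  if (sum(keep) < 0.25 * length(keep))
    stop("estimate_background: fewer than 25% of samples outside ",
         "comet exclusion zones")
  median(x$intensity[keep])
}

#' @rdname estimate_background
#' @param trace an [axon_trace()] along which to sample (image method).
#' @param band_px band width for profile sampling.
#' @export
estimate_background.image2d <- function(x, trace, comet_positions_um = NULL,
                                        exclusion_radius_um = 1,
                                        band_px = 3L, ...) {
  prof <- trace_profile(x, trace, band_px)
  estimate_background(prof, comet_positions_um, exclusion_radius_um)
}

#' Detect comets along a trace
#'
#' Peaks of the band-averaged along-trace profile after
#' difference-of-Gaussians filtering, kept when the smoothed intensity
#' exceeds background + `k_mad` robust noise sd, at least `min_sep_um`
#' apart. The background is estimated from the profile, refined once by
#' excluding a first round of detections.
#'
#' @param image an [image2d()].
#' @param trace an [axon_trace()].
#' @param psf_sigma_um PSF sigma (sets the DoG scales).
#' @param k_mad detection threshold in robust noise sds.
#' @param min_sep_um minimum separation between detections.
#' @param band_px band width for profile sampling.
#' @param background fixed background; `NULL` to estimate.
#' @param exclusion_radius_um exclusion half-width for the background
#'   refinement.
#' @return Sorted arclength positions (um) of detected comet tips.
#' @export
detect_comets <- function(image, trace, psf_sigma_um = 0.15, k_mad = 5,
                          min_sep_um = 0.5, band_px = 3L, background = NULL,
                          exclusion_radius_um = 1) {
  prof <- trace_profile(image, trace, band_px)
  bg <- background %||% estimate_background(prof)
  pks <- find_profile_peaks(prof, psf_sigma_um, k_mad, min_sep_um, bg)
  if (is.null(background) && length(pks)) {
    bg <- tryCatch(estimate_background(prof, pks, exclusion_radius_um),
                   error = function(e) bg)
    pks <- find_profile_peaks(prof, psf_sigma_um, k_mad, min_sep_um, bg)
  }
  pks
}

#' Measure one comet on an intensity profile
#'
#' The comet extent is the maximal contiguous run of samples around the
#' peak whose intensity exceeds `background + f * (peak - background)`;
#' length is the extent span, mean intensity the background-subtracted
#' mean over the extent, and the comet amount their product.
#'
#' @param profile an `intensity_profile` (its `background` field is used
#'   unless `background` is given).
#' @param peak_position_um arclength of the comet tip.
#' @param f fractional-peak threshold defining the comet edge.
#' @param background optional background override.
#' @return A `comet_measurement`: list with `length_um`,
#'   `mean_intensity`, `amount`, `peak_position_um`.
#' @export
measure_comet <- function(profile, peak_position_um, f = 0.2,
                          background = NULL) {
  stopifnot(inherits(profile, "intensity_profile"))
  bg <- background %||% profile$background
  x <- profile$intensity
  i <- which.min(abs(profile$arclength_um - peak_position_um))
  ## allow +-1 sample of slack around the nominal tip position
  nb <- max(1L, i - 1L):min(length(x), i + 1L)
  i <- nb[which.max(x[nb])]
  peak <- x[i]
  if (peak <= bg)
    stop(sprintf("no comet at position %.2f um (peak not above background)",
                 peak_position_um))
  thr <- bg + f * (peak - bg)
  lo <- i; while (lo > 1L && x[lo - 1L] > thr) lo <- lo - 1L
  hi <- i; while (hi < length(x) && x[hi + 1L] > thr) hi <- hi + 1L
  n_run <- hi - lo + 1L
  length_um <- n_run * profile$step_um
  mean_int <- mean(x[lo:hi] - bg)
  structure(list(length_um = length_um, mean_intensity = mean_int,
                 amount = mean_int * length_um,
                 peak_position_um = profile$arclength_um[i]),
            class = "comet_measurement")
}

#' @export
print.comet_measurement <- function(x, ...) {
  cat(sprintf("<comet_measurement> at %.2f um: length %.2f um, mean %.3g, amount %.3g\n",
              x$peak_position_um, x$length_um, x$mean_intensity, x$amount))
  invisible(x)
}

#' Detect and measure all comets along a trace
#'
#' Convenience wrapper: estimate background, detect comets and measure
#' each one.
#'
#' @inheritParams detect_comets
#' @param f fractional-peak threshold for the comet edge.
#' @return data.frame with one row per comet: `arclength_um`,
#'   `length_um`, `mean_intensity`, `amount`, plus attributes
#'   `background`.
#' @export
measure_comets <- function(image, trace, psf_sigma_um = 0.15, k_mad = 5,
                           min_sep_um = 0.5, band_px = 3L, f = 0.2,
                           exclusion_radius_um = 1) {
  prof <- trace_profile(image, trace, band_px)
  pks <- detect_comets(image, trace, psf_sigma_um, k_mad, min_sep_um,
                       band_px, exclusion_radius_um = exclusion_radius_um)
  bg <- if (length(pks))
    estimate_background(prof, pks, exclusion_radius_um)
  else estimate_background(prof)
  rows <- lapply(pks, function(p) {
    m <- tryCatch(measure_comet(profile_with_bg(prof, bg), p),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    data.frame(arclength_um = m$peak_position_um, length_um = m$length_um,
               mean_intensity = m$mean_intensity, amount = m$amount)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(arclength_um = numeric(), length_um = numeric(),
                      mean_intensity = numeric(), amount = numeric())
  attr(out, "background") <- bg
  out
}

profile_with_bg <- function(profile, bg) {
  profile$background <- bg
  profile
}

#' Mean lattice (shaft) intensity along a trace
#'
#' Background-subtracted band intensity along the trace, excluding a
#' window of `exclusion_radius_um` around each comet.
#'
#' @param image an [image2d()].
#' @param trace an [axon_trace()].
#' @param comet_positions_um comet tip positions to exclude (um); empty
#'   means no exclusion.
#' @param exclusion_radius_um exclusion half-width (um).
#' @param band_px band width for profile sampling.
#' @param background scalar baseline subtracted before averaging.
#' @return Scalar mean lattice intensity.
#' @export
lattice_intensity <- function(image, trace, comet_positions_um = numeric(),
                              exclusion_radius_um = 1, band_px = 3L,
                              background = 0) {
  prof <- trace_profile(image, trace, band_px)
  keep <- rep(TRUE, length(prof$arclength_um))
  for (p in comet_positions_um)
    keep <- keep & abs(prof$arclength_um - p) > exclusion_radius_um
  if (!any(keep))
    stop("lattice_intensity: exclusion zones cover the entire trace")
  mean(prof$intensity[keep] - background)
}
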