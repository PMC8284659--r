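## Along-trace intensity profiles: bilinear band-averaged sampling at 1 px
## arclength steps, 1D Gaussian / difference-of-Gaussians filtering and
## robust peak picking. Shared by the still-image comet measurements and
## the kymograph machinery.

## Vectorised bilinear interpolation; (x, y) are 0-based pixel-center
## coordinates. Returns NA outside the image.
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(x))
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 0 & y >= 0 & x <= nc - 1 & y <= nr - 1
  x0k <- pmin(x0[ok], nc - 2); y0k <- pmin(y0[ok], nr - 2)
  fxk <- x[ok] - x0k; fyk <- y[ok] - y0k
  i00 <- cbind(y0k + 1, x0k + 1); i01 <- cbind(y0k + 1, x0k + 2)
  i10 <- cbind(y0k + 2, x0k + 1); i11 <- cbind(y0k + 2, x0k + 2)
  out[ok] <- m[i00] * (1 - fxk) * (1 - fyk) + m[i01] * fxk * (1 - fyk) +
             m[i10] * (1 - fxk) * fyk + m[i11] * fxk * fyk
  out
}

#' Band-averaged intensity profile along a trace
#'
#' Samples the image along the trace at 1-pixel arclength steps with
#' bilinear interpolation, averaging across a perpendicular band of
#' `band_px` parallel lines (1 px apart, centred on the trace).
#'
#' @param image an [image2d()] (or a plain matrix plus `pixel_size_um`).
#' @param trace an [axon_trace()].
#' @param band_px odd band width in pixels.
#' @return An `intensity_profile`: list with `arclength_um` (uniform,
#'   strictly increasing), `intensity`, `step_um` and a `background`
#'   field initialised to 0.
#' @export
trace_profile <- function(image, trace, band_px = 3L) {
  stopifnot(inherits(image, "image2d"), inherits(trace, "axon_trace"))
  m <- image$pixels
  cl <- trace_cumlen_px(trace)
  total <- cl[length(cl)]
  if (total <= 0) stop("trace_profile: empty trace")
  s_px <- seq(0, floor(total))
  at <- trace_point_at(trace, s_px)
  nrm <- cbind(-at$tangent[, 2], at$tangent[, 1])
  offs <- seq(-(band_px - 1) / 2, (band_px - 1) / 2, by = 1)
  vals <- matrix(NA_real_, length(s_px), length(offs))
  for (j in seq_along(offs)) {
    xs <- at$xy[, 1] + offs[j] * nrm[, 1]
    ys <- at$xy[, 2] + offs[j] * nrm[, 2]
    vals[, j] <- bilinear_sample(m, xs, ys)
  }
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1, anyNA))[1]
    stop(sprintf("trace (band) leaves the image at arclength %.2f um",
                 s_px[bad] * image$pixel_size_um))
  }
  intensity_profile(s_px * image$pixel_size_um, rowMeans(vals))
}

#' Construct an intensity profile
#'
#' @param arclength_um strictly increasing, uniformly spaced positions.
#' @param intensity intensity values.
#' @param background scalar baseline (>= 0).
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(arclength_um, intensity, background = 0) {
  stopifnot(length(arclength_um) == length(intensity),
            length(arclength_um) >= 2L)
  d <- diff(arclength_um)
  if (any(d <= 0) || diff(range(d)) > 1e-8 * mean(d))
    stop("intensity_profile: positions must be strictly increasing with ",
         "uniform step")
  if (background < 0) stop("intensity_profile: background must be >= 0")
  structure(list(arclength_um = as.numeric(arclength_um),
                 intensity = as.numeric(intensity),
                 step_um = mean(d), background = background),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples, step %.4g um, background %g\n",
              length(x$intensity), x$step_um, x$background))
  invisible(x)
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## Convolution with reflected (mirrored) edges.
conv1d_reflect <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  pad <- c(x[pmin(r + 1L, n):2L], x, x[(n - 1L):pmax(n - r, 1L)])
  ## guard short signals
  if (length(pad) < n + 2L * r)
    pad <- c(rep(x[1], n + 2L * r - length(pad)), pad)
  out <- stats::filter(pad, k, sides = 2L)
  as.numeric(out[(r + 1L):(r + n)])
}

## Robust noise sd of a profile from first differences.
profile_noise_sd <- function(x) mad(diff(x)) / sqrt(2)

## Topographic prominence of sample i in profile g relative to floor bg:
## height above the higher of the two saddles separating it from higher
## ground; a side with no higher point uses bg as its saddle.
peak_prominence <- function(g, i, bg) {
  n <- length(g)
  left <- if (any(g[seq_len(i - 1)] > g[i])) {
    j <- max(which(g[seq_len(i - 1)] > g[i]))
    min(g[j:i])
  } else bg
  right <- if (i < n && any(g[(i + 1):n] > g[i])) {
    j <- i + min(which(g[(i + 1):n] > g[i]))
    min(g[i:j])
  } else bg
  g[i] - max(left, right)
}

## Peak picking on a 1D profile: local maxima of the DoG-filtered signal
## whose (smoothed) intensity exceeds background + k * noise. Sub-sample
## positions by parabolic interpolation; minimum separation enforced by
## keeping the stronger peak.
find_profile_peaks <- function(profile, psf_sigma_um, k_mad = 5,
                               min_sep_um = 0.5, background = NULL,
                               min_rel_height = 0.05) {
  x <- profile$intensity
  step <- profile$step_um
  bg <- background %||% profile$background
  s_px <- psf_sigma_um / step
  g1 <- conv1d_reflect(x, gauss_kernel1d(max(0.5 * s_px, 0.5)))
  g2 <- conv1d_reflect(x, gauss_kernel1d(2 * s_px))
  dog <- g1 - g2
  n <- length(x)
  if (n < 3L) return(numeric())
  is_max <- c(FALSE, dog[2:(n - 1)] > dog[1:(n - 2)] &
                     dog[2:(n - 1)] >= dog[3:n], FALSE)
  ## primary gate: smoothed intensity above background + k * noise;
  ## secondary gate: topographic prominence - the peak must stand on its
  ## own for a fraction of its height above background, which rejects
  ## shoulder bumps on a comet's tail regardless of the noise level
  ## (including noiseless renderings)
  thr <- bg + k_mad * profile_noise_sd(x)
  cand <- which(is_max & g1 > thr & dog > 0)
  ## a detection must coincide with local intensity structure: the g1
  ## maximum within the DoG support must be interior to the window (a
  ## monotone tail slope puts it at the window edge) and prominent
  w <- ceiling(4 * s_px)
  jmax <- vapply(cand, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    j <- lo - 1L + which.max(g1[lo:hi])
    if (j == lo || j == hi) return(NA_integer_)
    ## 0.15: a comet sitting on a brighter neighbour's tail still shows
    ## ~20% relative prominence, while tail shoulders and rendering
    ## ripple stay below ~6%
    if (peak_prominence(g1, j, bg) >= 0.15 * (g1[j] - bg)) as.integer(j)
    else NA_integer_
  }, 0L)
  cand <- unique(jmax[!is.na(jmax)])
  ## the ends of the profile are inside the DoG filter support, where the
  ## lattice terminus mimics a comet edge; peaks there are not trusted
  edge <- ceiling(2 * 2 * s_px)
  cand <- cand[cand > edge & cand <= n - edge]
  if (length(cand) == 0L) return(numeric())
  ## dynamic-range floor: peaks far below the strongest one are residual
  ## tail structure, not comets (EB comet brightness varies a few-fold,
  ## not by a factor of twenty)
  h <- g1[cand] - bg
  cand <- cand[h >= min_rel_height * max(h)]
  ## parabolic sub-sample refinement on a more heavily smoothed profile
  ## (lower localisation noise; the asymmetry bias is the same in every
  ## frame, so it cancels in velocities and lifetimes)
  gr <- conv1d_reflect(x, gauss_kernel1d(max(s_px, 1)))
  pos <- vapply(cand, function(i) {
    lo <- max(2L, i - 2L); hi <- min(n - 1L, i + 2L)
    j <- (lo:hi)[which.max(gr[lo:hi])]
    a <- gr[j - 1]; b <- gr[j]; c <- gr[j + 1]
    den <- a - 2 * b + c
    fr <- if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (a - c) / den))
    profile$arclength_um[j] + fr * step
  }, 0)
  hgt <- g1[cand]
  keep <- logical(length(cand))
  for (i in order(hgt, decreasing = TRUE)) {
    if (!any(keep & abs(pos - pos[i]) < min_sep_um)) keep[i] <- TRUE
  }
  sort(pos[keep])
}
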