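#' axonmt: quantification of axonal microtubule plus-end dynamics
#'
#' Containers used throughout the package. All coordinates are 0-based with
#' x = column index and y = row index, referring to pixel centers. Physical
#' units are micrometres (um) and seconds (s); pixels appear only at the
#' image interface.
#'
#' @name axonmt-package
#' @importFrom stats approx coef lm mad median pchisq pnorm pt pwilcox
#'   quantile rbinom rexp rnorm rpois runif setNames
#' @importFrom utils head tail
"_PACKAGE"

#' Single calibrated fluorescence image
#'
#' @param pixels numeric matrix of intensities (rows x cols).
#' @param pixel_size_um pixel size in um/pixel, > 0.
#' @return An object of class `image2d`.
#' @export
image2d <- function(pixels, pixel_size_um) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("image2d: pixel intensities must be finite numerics")
  check_pixel_size(pixel_size_um)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "image2d")
}

#' Calibrated time-lapse stack
#'
#' @param frames numeric array T x rows x cols, T >= 2.
#' @param pixel_size_um pixel size in um/pixel.
#' @param frame_interval_s frame interval in seconds, > 0.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size_um, frame_interval_s) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("movie_stack: frames must be a T x rows x cols array")
  if (dim(frames)[1] < 2L)
    stop("movie_stack: T >= 2 frames required")
  check_pixel_size(pixel_size_um)
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0)
    stop("movie_stack: frame_interval_s must be a positive scalar")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "movie_stack")
}

#' Polyline axon trace (soma end first)
#'
#' @param vertices two-column matrix of (x, y) pixel coordinates, the soma
#'   end first. 0-based, pixel-center convention.
#' @param pixel_size_um pixel size in um/pixel.
#' @return An object of class `axon_trace`.
#' @export
axon_trace <- function(vertices, pixel_size_um) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("axon_trace: need a 2-column matrix with >= 2 vertices")
  if (any(!is.finite(vertices)))
    stop("axon_trace: vertices must be finite")
  d <- sqrt(rowSums(diff(vertices)^2))
  if (any(d == 0))
    stop("axon_trace: consecutive vertices must be distinct")
  check_pixel_size(pixel_size_um)
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, pixel_size_um = pixel_size_um),
            class = "axon_trace")
}

#' Polygon region of interest
#'
#' @param vertices two-column matrix of (x, y) pixel coordinates.
#' @param label one of `"curl"`, `"swelling"`, `"swelling_with_curl"`.
#' @return An object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices, label = "curl") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("polygon_roi: need a 2-column matrix with >= 3 vertices")
  label <- match.arg(label, c("curl", "swelling", "swelling_with_curl"))
  if (!polygon_is_simple(vertices))
    stop("polygon_roi: polygon must be simple (non-self-intersecting)")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, label = label), class = "polygon_roi")
}

check_pixel_size <- function(pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar (um/pixel); ",
         "calibration is never assumed")
  invisible(pixel_size_um)
}

## Proper segment-intersection test; shared edges at endpoints allowed.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (anyDuplicated(v[seq_len(n), , drop = FALSE])) return(FALSE)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next   # first and last edge share a vertex
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
  (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.4g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d frames of %d x %d px, %.4g um/px, dt = %g s\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' @export
print.axon_trace <- function(x, ...) {
  cat(sprintf("<axon_trace> %d vertices, arclength %.2f um (%.4g um/px)\n",
              nrow(x$vertices), trace_arclength_um(x), x$pixel_size_um))
  invisible(x)
}

#' @export
print.polygon_roi <- function(x, ...) {
  cat(sprintf("<polygon_roi> label '%s', %d vertices\n",
              x$label, nrow(x$vertices)))
  invisible(x)
}

#' Total arclength of a trace in micrometres
#'
#' Sum of Euclidean segment lengths scaled by the pixel size.
#'
#' @param trace an [axon_trace()].
#' @return Arclength in um.
#' @export
trace_arclength_um <- function(trace) {
  stopifnot(inherits(trace, "axon_trace"))
  sum(sqrt(rowSums(diff(trace$vertices)^2))) * trace$pixel_size_um
}

## Cumulative arclength (px) at each vertex, starting at 0.
trace_cumlen_px <- function(trace) {
  c(0, cumsum(sqrt(rowSums(diff(trace$vertices)^2))))
}

## Point (x, y) and unit tangent at arclength positions s_px (vectorised).
trace_point_at <- function(trace, s_px) {
  v <- trace$vertices
  cl <- trace_cumlen_px(trace)
  total <- cl[length(cl)]
  s_px <- pmin(pmax(s_px, 0), total)
  seg <- findInterval(s_px, cl, rightmost.closed = TRUE)
  seg <- pmin(seg, nrow(v) - 1L)
  p0 <- v[seg, , drop = FALSE]
  p1 <- v[seg + 1L, , drop = FALSE]
  len <- sqrt(rowSums((p1 - p0)^2))
  f <- (s_px - cl[seg]) / len
  pt <- p0 + (p1 - p0) * f
  tang <- (p1 - p0) / len
  list(xy = pt, tangent = tang)
}

## Run code with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
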