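## Axon morphometrics: axon length, polygon areas, the microtubule
## disorganisation index (MDI) and swelling counts.

#' Axon length in micrometres
#'
#' Sum of Euclidean segment lengths of the trace polyline (cell body to
#' growth cone tip) scaled by the pixel size.
#'
#' @param trace an [axon_trace()].
#' @return Length in um.
#' @export
axon_length <- function(trace) {
  stopifnot(inherits(trace, "axon_trace"))
  len <- trace_arclength_um(trace)
  if (len <= 0) stop("axon_length: degenerate trace")
  len
}

#' Polygon area in square micrometres
#'
#' Shoelace area of a simple polygon scaled by the squared pixel size.
#' Orientation does not matter.
#'
#' @param poly a [polygon_roi()] or a 2-column vertex matrix.
#' @param pixel_size_um pixel size in um.
#' @return Area in um^2.
#' @export
polygon_area <- function(poly, pixel_size_um) {
  check_pixel_size(pixel_size_um)
  v <- if (inherits(poly, "polygon_roi")) poly$vertices else as.matrix(poly)
  if (nrow(v) < 3L) stop("polygon_area: need >= 3 vertices")
  if (!inherits(poly, "polygon_roi") && !polygon_is_simple(v))
    stop("polygon_area: polygon must be simple (non-self-intersecting)")
  shoelace_area(v) * pixel_size_um^2
}

#' Microtubule disorganisation index (MDI)
#'
#' Total area of disorganised (curled) regions divided by the axon
#' length times a reference axon diameter (default 0.5 um) - i.e. the
#' curl area in units of the area the axon would occupy if its
#' microtubules were properly bundled. Multiple curl regions are summed.
#'
#' @param curl_polys list of [polygon_roi()]s (label `"curl"`), possibly
#'   empty.
#' @param trace the axon's [axon_trace()].
#' @param reference_diameter_um reference axon diameter in um.
#' @return An `mdi_result`: list with `axon_length_um`, `curl_area_um2`,
#'   `reference_diameter_um`, `mdi`.
#' @export
mdi <- function(curl_polys, trace, reference_diameter_um = 0.5) {
  stopifnot(inherits(trace, "axon_trace"))
  if (reference_diameter_um <= 0)
    stop("mdi: reference_diameter_um must be positive")
  len <- axon_length(trace)
  area <- if (length(curl_polys))
    sum(vapply(curl_polys, polygon_area, 0, pixel_size_um = trace$pixel_size_um))
  else 0
  structure(list(axon_length_um = len, curl_area_um2 = area,
                 reference_diameter_um = reference_diameter_um,
                 mdi = area / (len * reference_diameter_um)),
            class = "mdi_result")
}

#' @export
print.mdi_result <- function(x, ...) {
  cat(sprintf("<mdi_result> length %.2f um, curl area %.2f um^2, MDI %.3f\n",
              x$axon_length_um, x$curl_area_um2, x$mdi))
  invisible(x)
}

#' Axonal swelling counts and per-axon rates
#'
#' Counts annotated swellings and the subset with microtubule curling;
#' a `swelling_with_curl` annotation counts as a swelling too.
#'
#' @param annotations list of [polygon_roi()]s with labels `"swelling"`
#'   or `"swelling_with_curl"` pooled over the scored axons.
#' @param n_axons number of axons scored (> 0).
#' @return List with `n_axons`, `n_swellings`, `n_swellings_with_curl`,
#'   `swellings_per_axon`, `swellings_with_curl_per_axon`.
#' @export
swelling_counts <- function(annotations, n_axons) {
  if (!is.numeric(n_axons) || n_axons <= 0)
    stop("swelling_counts: n_axons must be > 0")
  labels <- vapply(annotations, `[[`, "", "label")
  if (any(!labels %in% c("swelling", "swelling_with_curl")))
    stop("swelling_counts: labels must be 'swelling' or 'swelling_with_curl'")
  n_sw <- length(labels)
  n_swc <- sum(labels == "swelling_with_curl")
  list(n_axons = n_axons, n_swellings = n_sw,
       n_swellings_with_curl = n_swc,
       swellings_per_axon = n_sw / n_axons,
       swellings_with_curl_per_axon = n_swc / n_axons)
}
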