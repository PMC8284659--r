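## TIFF stack and ROI I/O. Calibration is never assumed: it comes from a
## sidecar JSON (written alongside every stack) or from explicit arguments.
##
## Intensity storage: `tiff` stores samples on a uniform [0, 1] grid, so
## stacks are written as (value - offset) / scale with scale a power of
## two and offset = -scale/2, both recorded in the sidecar together with
## an integer_data flag. Integer data round-trips exactly (rounded on
## read); other data round-trips to within 2^-32 of the recorded range.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
}

pow2_ceiling <- function(x) 2^ceiling(log2(max(x, 1)))

#' Write a calibrated time-lapse stack as multi-page TIFF
#'
#' One 32-bit float page per frame plus a sidecar JSON
#' (`<path-minus-ext>.json`) holding `pixel_size_um`, `frame_interval_s`
#' and the intensity scaling applied for storage.
#'
#' @param stack a [movie_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$frames)
  scale <- pow2_ceiling(2 * max(abs(stack$frames), 1))
  pages <- lapply(seq_len(d[1]), function(k)
    stack$frames[k, , ] / scale + 0.5)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         frame_interval_s = stack$frame_interval_s,
         intensity_scale = scale, intensity_offset = -scale / 2,
         integer_data = all(stack$frames == round(stack$frames))),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated time-lapse stack
#'
#' @param path TIFF path (multi-page; >= 2 pages required for a movie).
#' @param pixel_size_um,frame_interval_s calibration overrides; required
#'   when no sidecar JSON is present.
#' @return A [movie_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL) {
  meta <- read_sidecar(path)
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
  if (is.null(pixel_size_um) || is.null(frame_interval_s))
    stop("read_stack: no calibration; supply pixel_size_um and ",
         "frame_interval_s or provide a sidecar JSON")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L)
    stop("read_stack: T >= 2 frames required; got ", length(pages),
         " page(s)")
  frames <- array(0, c(length(pages), dim(pages[[1]])))
  for (k in seq_along(pages)) frames[k, , ] <- decode_intensity(pages[[k]], meta)
  movie_stack(frames, pixel_size_um, frame_interval_s)
}

decode_intensity <- function(m, meta) {
  if (is.null(meta$intensity_scale)) return(m)
  v <- m * meta$intensity_scale + (meta$intensity_offset %||% 0)
  ## 32-bit samples are stored on a uniform grid over the recorded
  ## range; rounding restores integer-valued data exactly
  if (isTRUE(meta$integer_data)) v <- round(v)
  v
}

#' Write / read a single calibrated image
#'
#' @param image an [image2d()].
#' @param path TIFF path.
#' @return `path` invisibly (write); an [image2d()] (read).
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image2d"))
  scale <- pow2_ceiling(2 * max(abs(image$pixels), 1))
  tiff::writeTIFF(image$pixels / scale + 0.5, path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um,
         intensity_scale = scale, intensity_offset = -scale / 2,
         integer_data = all(image$pixels == round(image$pixels))),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @param pixel_size_um calibration override; required without a sidecar.
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  meta <- read_sidecar(path)
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(pixel_size_um))
    stop("read_image: no calibration; supply pixel_size_um or a sidecar JSON")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  image2d(decode_intensity(m, meta), pixel_size_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- ROI dialect ----------------------------------------------------------

#' Write traces and polygon ROIs to the package's JSON dialect
#'
#' @param traces list of [axon_trace()] objects.
#' @param polygons list of [polygon_roi()] objects.
#' @param path output `.json` path.
#' @param pixel_size_um calibration stored with the file (defaults to the
#'   first trace's).
#' @return `path`, invisibly.
#' @export
write_rois <- function(traces, polygons, path, pixel_size_um = NULL) {
  if (is.null(pixel_size_um) && length(traces))
    pixel_size_um <- traces[[1]]$pixel_size_um
  obj <- list(
    pixel_size_um = pixel_size_um,
    traces = lapply(traces, function(tr) list(points = unname(tr$vertices))),
    polygons = lapply(polygons, function(p)
      list(label = p$label, points = unname(p$vertices))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read traces and polygon ROIs
#'
#' Accepts the package's JSON dialect, its CSV alternative (columns
#' `roi_id, type, label, x, y`, one vertex per row), or ImageJ `.roi` /
#' `.zip` files (polyline/freeline become traces; polygon/freehand/traced
#' become polygons). ImageJ integer coordinates are pixel-corner based and
#' are shifted by -0.5 px on both axes into the package's pixel-center
#' convention.
#'
#' @param path input file.
#' @param pixel_size_um calibration override; required when the file does
#'   not record one (always the case for ImageJ ROIs).
#' @return A list with `traces` (list of [axon_trace()]) and `polygons`
#'   (list of [polygon_roi()]).
#' @export
read_rois <- function(path, pixel_size_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = read_rois_json(path, pixel_size_um),
    csv = read_rois_csv(path, pixel_size_um),
    roi = read_rois_imagej(list(path), pixel_size_um),
    zip = {
      exdir <- tempfile("rois")
      files <- utils::unzip(path, exdir = exdir)
      on.exit(unlink(exdir, recursive = TRUE))
      read_rois_imagej(as.list(files[grepl("\\.roi$", files)]), pixel_size_um)
    },
    stop("read_rois: unsupported file type '.", ext, "'"))
}

read_rois_json <- function(path, pixel_size_um) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pixel_size_um <- pixel_size_um %||% obj$pixel_size_um
  if (is.null(pixel_size_um))
    stop("read_rois: no calibration; supply pixel_size_um")
  pts <- function(p) {
    m <- if (is.matrix(p)) p else do.call(rbind, p)
    matrix(as.numeric(m), ncol = 2)
  }
  list(
    traces = lapply(obj$traces, function(tr)
      axon_trace(pts(tr$points), pixel_size_um)),
    polygons = lapply(obj$polygons, function(p)
      polygon_roi(pts(p$points), p$label %||% "curl")))
}

read_rois_csv <- function(path, pixel_size_um) {
  if (is.null(pixel_size_um))
    stop("read_rois: no calibration; supply pixel_size_um")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "type", "label", "x", "y")
  if (!all(need %in% names(df)))
    stop("read_rois: CSV must have columns ", paste(need, collapse = ", "))
  traces <- list(); polygons <- list()
  for (id in unique(df$roi_id)) {
    sub <- df[df$roi_id == id, ]
    v <- cbind(sub$x, sub$y)
    if (sub$type[1] == "trace")
      traces[[length(traces) + 1L]] <- axon_trace(v, pixel_size_um)
    else if (sub$type[1] == "polygon")
      polygons[[length(polygons) + 1L]] <- polygon_roi(v, sub$label[1])
    else stop("read_rois: unknown ROI type '", sub$type[1], "'")
  }
  list(traces = traces, polygons = polygons)
}

## Minimal ImageJ .roi reader (integer-coordinate polyline/freeline/
## polygon/freehand/traced subtypes).
read_rois_imagej <- function(paths, pixel_size_um) {
  if (is.null(pixel_size_um))
    stop("read_rois: ImageJ ROIs carry no calibration; supply pixel_size_um")
  traces <- list(); polygons <- list()
  type_names <- c("polygon", "rect", "oval", "line", "freeline", "polyline",
                  "noRoi", "freehand", "traced", "angle", "point")
  for (p in paths) {
    raw <- readBin(p, "raw", file.size(p))
    if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
      stop("read_rois: '", p, "' is not an ImageJ ROI file")
    be_short <- function(off, n = 1L)
      readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
              signed = TRUE, endian = "big")
    type <- as.integer(raw[7L])
    top <- be_short(8L); left <- be_short(10L)
    n <- be_short(16L)
    if (!type %in% c(0L, 4L, 5L, 7L, 8L))
      stop("read_rois: unsupported ImageJ ROI subtype '",
           type_names[type + 1L], "'")
    xs <- be_short(64L, n); ys <- be_short(64L + 2L * n, n)
    v <- cbind(left + xs - 0.5, top + ys - 0.5)
    if (type %in% c(4L, 5L))
      traces[[length(traces) + 1L]] <- axon_trace(v, pixel_size_um)
    else
      polygons[[length(polygons) + 1L]] <- polygon_roi(v, "curl")
  }
  list(traces = traces, polygons = polygons)
}
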