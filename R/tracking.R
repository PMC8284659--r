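## 2D plus-end comet detection and linking with the printed
## plusTipTracker-style parameter semantics: bounded search radius with a
## fluctuation (pause) exemption, forward/backward angle gates, a
## shrinkage bound on backward steps, gap closing up to a maximum gap
## length and a minimum observed track length.

#' Tracking parameters
#'
#' Defaults are the published parameter set for 2 s-interval plus-end
#' marker movies: maximum gap length 8 frames, minimum track length 3
#' frames, search radius range 5-12 px, maximum forward angle 50 deg,
#' maximum backward angle 10 deg, maximum shrinkage factor 0.8,
#' fluctuation radius 2.5 px.
#'
#' Semantics as implemented here: a frame-to-frame step is feasible when
#' its length is at most the upper search radius and either at least the
#' lower radius or at most the fluctuation radius (a pause). Steps longer
#' than the fluctuation radius must deviate from the current track
#' heading by at most the forward angle, or - as backward (shrinkage)
#' steps - lie within the backward angle of the reversed heading and be
#' no longer than the shrinkage factor times the mean forward step.
#'
#' @param max_gap_frames maximum number of consecutive missed frames
#'   bridged by gap closing.
#' @param min_track_frames minimum number of observed points per track.
#' @param search_radius_px `c(lower, upper)` step-length bounds in px.
#' @param max_forward_angle_deg forward direction-change bound.
#' @param max_backward_angle_deg backward direction bound.
#' @param max_shrinkage_factor backward step length bound as a fraction
#'   of the mean forward step.
#' @param fluctuation_radius_px displacements at or below this are
#'   pauses, exempt from the lower radius and angle gates.
#' @param frame_interval_s acquisition interval in seconds.
#' @return A validated list of class `tracking_params`.
#' @export
tracking_params <- function(max_gap_frames = 8L, min_track_frames = 3L,
                            search_radius_px = c(5, 12),
                            max_forward_angle_deg = 50,
                            max_backward_angle_deg = 10,
                            max_shrinkage_factor = 0.8,
                            fluctuation_radius_px = 2.5,
                            frame_interval_s = 2) {
  p <- list(max_gap_frames = as.integer(max_gap_frames),
            min_track_frames = as.integer(min_track_frames),
            search_radius_px = as.numeric(search_radius_px),
            max_forward_angle_deg = max_forward_angle_deg,
            max_backward_angle_deg = max_backward_angle_deg,
            max_shrinkage_factor = max_shrinkage_factor,
            fluctuation_radius_px = fluctuation_radius_px,
            frame_interval_s = frame_interval_s)
  if (length(p$search_radius_px) != 2L || any(p$search_radius_px <= 0) ||
      diff(p$search_radius_px) < 0)
    stop("tracking_params: search_radius_px must be positive c(lower, upper)")
  if (p$max_forward_angle_deg <= 0 || p$max_forward_angle_deg >= 180 ||
      p$max_backward_angle_deg <= 0 || p$max_backward_angle_deg >= 180)
    stop("tracking_params: angles must lie in (0, 180)")
  if (p$min_track_frames < 2L)
    stop("tracking_params: min_track_frames must be >= 2")
  if (p$max_gap_frames < 0L) stop("tracking_params: max_gap_frames >= 0")
  if (p$fluctuation_radius_px <= 0 || p$max_shrinkage_factor <= 0)
    stop("tracking_params: radii and factors must be positive")
  if (p$frame_interval_s <= 0)
    stop("tracking_params: frame_interval_s must be positive")
  structure(p, class = "tracking_params")
}

#' @export
print.tracking_params <- function(x, ...) {
  cat(sprintf(paste0("<tracking_params> gap <= %d, length >= %d, radius ",
                     "[%g, %g] px, fwd <= %g deg, bwd <= %g deg, ",
                     "shrink <= %g, fluct %g px, dt %g s\n"),
              x$max_gap_frames, x$min_track_frames, x$search_radius_px[1],
              x$search_radius_px[2], x$max_forward_angle_deg,
              x$max_backward_angle_deg, x$max_shrinkage_factor,
              x$fluctuation_radius_px, x$frame_interval_s))
  invisible(x)
}

#' Detect comet particles in a single frame
#'
#' Difference-of-Gaussians filtering, 8-neighbour local maxima above a
#' robust threshold, and intensity-weighted centroid refinement.
#' Deterministic output ordered by (y, x).
#'
#' @param frame an [image2d()].
#' @param psf_sigma_um PSF sigma (sets DoG scales and centroid window).
#' @param k_mad detection threshold in robust sds of the DoG response.
#' @param min_sep_px non-maximum-suppression radius: an elongated comet
#'   streak yields secondary maxima along its tail, which are merged
#'   into the strongest one within this radius.
#' @return data.frame with columns `x`, `y` (0-based pixel-center
#'   coordinates) and `intensity`.
#' @export
detect_particles <- function(frame, psf_sigma_um = 0.15, k_mad = 5,
                             min_sep_px = 6, comet_tail_um = 1) {
  stopifnot(inherits(frame, "image2d"))
  m <- frame$pixels
  px <- frame$pixel_size_um
  s_px <- max(psf_sigma_um / px, 0.6)
  s1 <- max(0.5 * s_px, 0.5)
  g1 <- EBImage::gblur(m, sigma = s1)
  g2 <- EBImage::gblur(m, sigma = 2 * s_px)
  d <- g1 - g2
  ## primary gate on the smoothed intensity (comets are sparse, so the
  ## median/mad of g1 estimate background and noise); tail-side
  ## secondary maxima are absorbed by the comet-length NMS below
  thr <- median(g1) + k_mad * mad(g1)
  nr <- nrow(d); nc <- ncol(d)
  ctr <- d[2:(nr - 1), 2:(nc - 1)]
  ismax <- ctr > 0 & g1[2:(nr - 1), 2:(nc - 1)] > thr &
    ctr >  d[1:(nr - 2), 2:(nc - 1)] & ctr >= d[3:nr, 2:(nc - 1)] &
    ctr >  d[2:(nr - 1), 1:(nc - 2)] & ctr >= d[2:(nr - 1), 3:nc] &
    ctr >  d[1:(nr - 2), 1:(nc - 2)] & ctr >= d[3:nr, 3:nc] &
    ctr >= d[1:(nr - 2), 3:nc]       & ctr >  d[3:nr, 1:(nc - 2)]
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x = numeric(), y = numeric(), intensity = numeric()))
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  ## a candidate must coincide with local intensity structure: if the g1
  ## maximum of its neighbourhood sits on the window boundary the
  ## candidate lies on a monotone slope (a comet tail), not at a comet
  wb <- 6L
  interior <- vapply(seq_along(rows), function(i) {
    r0 <- max(1L, rows[i] - wb); r1 <- min(nr, rows[i] + wb)
    c0 <- max(1L, cols[i] - wb); c1 <- min(nc, cols[i] + wb)
    win <- g1[r0:r1, c0:c1, drop = FALSE]
    a <- which(win == max(win), arr.ind = TRUE)[1, ]
    a[1] > 1L && a[1] < nrow(win) && a[2] > 1L && a[2] < ncol(win)
  }, TRUE)
  rows <- rows[interior]; cols <- cols[interior]
  if (length(rows) == 0L)
    return(data.frame(x = numeric(), y = numeric(), intensity = numeric()))
  ## sub-pixel tip localisation: where the local structure is clearly
  ## elongated, estimate the comet axis from intensity second moments
  ## and slide the comet template (front + exponential tail, blurred by
  ## PSF and filter) along it - a matched filter whose maximum is an
  ## unbiased tip estimate; otherwise fall back to a parabolic
  ## refinement of the DoG peak
  tmpl <- comet_template_fun(psf_sigma_um, s1 * px, comet_tail_um, px)
  ks <- seq(-1.2 * comet_tail_um / px, 4, by = 0.5)
  Tm <- tmpl(ks); Tm <- Tm - mean(Tm)
  bgm <- median(g1)
  noise_g1 <- mad(g1)
  res <- t(vapply(seq_along(rows), function(i) {
    r <- rows[i]; c <- cols[i]
    pr <- function(a, b, cc) {
      den <- a - 2 * b + cc
      if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (a - cc) / den))
    }
    fy <- pr(d[r - 1L, c], d[r, c], d[r + 1L, c])
    fx <- pr(d[r, c - 1L], d[r, c], d[r, c + 1L])
    fallback <- c((c - 1L) + fx, (r - 1L) + fy, m[r, c])
    ## comet axis from the candidate-to-centroid vector of the local
    ## noise-cut excess intensity: the tail pulls the centroid backward,
    ## giving the axis and the tail side in one step
    w <- 9L
    r0 <- max(1L, r - w); r1 <- min(nr, r + w)
    c0 <- max(1L, c - w); c1 <- min(nc, c + w)
    W <- pmax(g1[r0:r1, c0:c1, drop = FALSE] - (bgm + 2 * noise_g1), 0)
    sw <- sum(W)
    if (sw <= 0) return(fallback)
    xs <- (c0:c1) - c; ys <- (r0:r1) - r
    mx <- sum(t(W) * xs) / sw; my <- sum(W * ys) / sw
    off <- sqrt(mx^2 + my^2)
    if (off < 1) return(fallback)      # no clear tail direction
    u <- -c(mx, my) / off              # towards the tip
    ## the NMS-selected anchor can sit a few px down the tail, so the
    ## search reaches further towards the tip than backwards
    shifts <- seq(-2, 6, by = 0.25)
    cc <- vapply(shifts, function(s) {
      v <- bilinear_sample(g1, (c - 1L) + u[1] * (ks + s),
                           (r - 1L) + u[2] * (ks + s))
      v[is.na(v)] <- bgm
      sum((v - mean(v)) * Tm)
    }, 0)
    j <- which.max(cc)
    fr <- if (j > 1L && j < length(shifts))
      pr(cc[j - 1], cc[j], cc[j + 1]) else 0
    s_star <- shifts[j] + fr * 0.25
    c((c - 1L) + u[1] * s_star, (r - 1L) + u[2] * s_star, m[r, c])
  }, numeric(3)))
  out <- data.frame(x = res[, 1], y = res[, 2], intensity = res[, 3])
  ## non-maximum suppression within min_sep_px, keyed on the DoG
  ## response (the raw pixel value is noise-dominated and would let a
  ## tail-side maximum outrank the comet core)
  out$response <- d[cbind(rows, cols)]
  o <- order(out$response, decreasing = TRUE)
  keep <- logical(nrow(out))
  for (i in o) {
    if (!any(keep & (out$x - out$x[i])^2 + (out$y - out$y[i])^2 <
             min_sep_px^2)) keep[i] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  out$response <- NULL
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Comet template as a function of position along the axis in pixels
## (positive = ahead of the tip): the intrinsic profile blurred by the
## PSF and the detection filter.
comet_template_fun <- function(psf_sigma_um, filter_sigma_um, tail_um, px) {
  sig_tot <- sqrt(psf_sigma_um^2 + filter_sigma_um^2)
  h <- 0.05
  dg <- seq(-8 * tail_um, 8 * tail_um, by = h)
  prof <- comet_profile(dg, sig_tot, tail_um)
  kern <- exp(-seq(-4 * sig_tot, 4 * sig_tot, by = h)^2 / (2 * sig_tot^2))
  kern <- kern / sum(kern)
  nb <- length(kern)
  padded <- c(rep(0, nb), prof, rep(0, nb))
  sm <- stats::filter(padded, kern, sides = 2)
  sm <- as.numeric(sm[(nb + 1):(nb + length(dg))])
  approxfun(dg / px, sm, rule = 2)
}

## ---- linking --------------------------------------------------------------

vec_angle_deg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

## Step feasibility given the track's state; returns "forward", "pause",
## "backward" or NA (infeasible).
classify_step <- function(step, heading, mean_fwd, params) {
  d <- sqrt(sum(step^2))
  if (d > params$search_radius_px[2]) return(NA_character_)
  if (d <= params$fluctuation_radius_px) return("pause")
  if (d < params$search_radius_px[1]) return(NA_character_)
  if (is.null(heading)) return("forward")
  ang <- vec_angle_deg(step, heading)
  if (ang <= params$max_forward_angle_deg) return("forward")
  if (ang >= 180 - params$max_backward_angle_deg &&
      !is.na(mean_fwd) && d <= params$max_shrinkage_factor * mean_fwd)
    return("backward")
  NA_character_
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame assignment minimises the total squared displacement
#' (optimal bipartite assignment with a birth/death alternative costed at
#' the squared upper search radius), subject to the feasibility gates of
#' [tracking_params()]. Track ends are then reconnected across gaps of up
#' to `max_gap_frames` missed frames when the position extrapolated from
#' the track's heading lies within the upper search radius scaled by the
#' gap length. Tracks with fewer than `min_track_frames` observed points
#' are discarded.
#'
#' @param detections list with one data.frame (columns `x`, `y`) per
#'   frame, in frame order; empty data.frames mark frames without
#'   detections. Optional names must be sorted frame numbers.
#' @param params a [tracking_params()].
#' @return List of `plusend_track` objects: `points` (data.frame `frame`,
#'   `x`, `y`), `gap_frames` (number of bridged frames).
#' @export
link_tracks <- function(detections, params = tracking_params()) {
  stopifnot(is.list(detections), inherits(params, "tracking_params"))
  if (!is.null(names(detections))) {
    fr <- suppressWarnings(as.numeric(names(detections)))
    if (!anyNA(fr) && is.unsorted(fr, strictly = TRUE))
      stop("link_tracks: detection frames must be sorted")
  }
  Tn <- length(detections)
  active <- list()  # list(points = matrix(frame, x, y), heading, fwd_steps)
  finished <- list()
  for (t in seq_len(Tn)) {
    det <- detections[[t]]
    ## frame-to-frame only: tracks not extended last frame are finished
    if (length(active)) {
      lastf <- vapply(active, function(a) a$points[nrow(a$points), 1], 0)
      fin <- lastf < t - 1
      finished <- c(finished, active[fin])
      active <- active[!fin]
    }
    nd <- if (is.null(det)) 0L else nrow(det)
    nt <- length(active)
    if (nd > 0L && nt > 0L) {
      b <- params$search_radius_px[2]^2
      INF <- 1e12
      C <- matrix(INF, nt + nd, nd + nt)
      kind <- matrix(NA_character_, nt, nd)
      for (i in seq_len(nt)) {
        last <- active[[i]]$points[nrow(active[[i]]$points), 2:3]
        mf <- if (length(active[[i]]$fwd_steps))
          mean(active[[i]]$fwd_steps) else NA_real_
        for (j in seq_len(nd)) {
          step <- c(det$x[j], det$y[j]) - last
          k <- classify_step(step, active[[i]]$heading, mf, params)
          if (!is.na(k)) {
            kind[i, j] <- k
            ## backward (shrinkage) steps are exceptional: penalise them
            ## so they never outbid a feasible forward continuation
            C[i, j] <- sum(step^2) * if (k == "backward") 4 else 1
          }
        }
      }
      for (i in seq_len(nt)) C[i, nd + i] <- b
      for (j in seq_len(nd)) C[nt + j, j] <- b
      C[(nt + 1):(nt + nd), (nd + 1):(nd + nt)] <- 0
      asg <- solve_assignment(C)
      linked_det <- logical(nd)
      for (i in seq_len(nt)) {
        j <- asg[i]
        if (j <= nd && C[i, j] < INF) {
          linked_det[j] <- TRUE
          active[[i]] <- extend_track(active[[i]], t, c(det$x[j], det$y[j]),
                                      kind[i, j], params)
        }
      }
      for (j in which(!linked_det))
        active[[length(active) + 1L]] <- new_track(t, c(det$x[j], det$y[j]))
    } else if (nd > 0L) {
      for (j in seq_len(nd))
        active[[length(active) + 1L]] <- new_track(t, c(det$x[j], det$y[j]))
    }
  }
  segs <- c(finished, active)
  segs <- close_gaps(segs, params)
  segs <- Filter(function(a) nrow(a$points) >= params$min_track_frames, segs)
  lapply(segs, function(a) {
    pts <- data.frame(frame = a$points[, 1], x = a$points[, 2],
                      y = a$points[, 3])
    span <- max(pts$frame) - min(pts$frame) + 1
    structure(list(points = pts, gap_frames = span - nrow(pts)),
              class = "plusend_track")
  })
}

new_track <- function(frame, pos) {
  list(points = matrix(c(frame, pos), 1L), heading = NULL,
       fwd_steps = numeric())
}

extend_track <- function(a, frame, pos, kind, params) {
  step <- pos - a$points[nrow(a$points), 2:3]
  a$points <- rbind(a$points, c(frame, pos))
  if (identical(kind, "forward") &&
      sqrt(sum(step^2)) > params$fluctuation_radius_px) {
    a$heading <- step
    a$fwd_steps <- c(a$fwd_steps, sqrt(sum(step^2)))
  }
  a
}

## Greedy gap closing on extrapolation error; merged tracks can chain.
## Segments abutting in time (no missing frame) arise when one outlier
## detection made a step infeasible; those are repaired by trimming the
## single offending junction point and re-validating the merge.
close_gaps <- function(segs, params) {
  if (params$max_gap_frames < 1L || length(segs) < 2L) return(segs)
  repeat {
    n <- length(segs)
    info <- lapply(segs, function(a) {
      p <- a$points
      list(f0 = p[1, 1], p0 = p[1, 2:3], f1 = p[nrow(p), 1],
           p1 = p[nrow(p), 2:3], heading = a$heading,
           mstep = if (length(a$fwd_steps)) mean(a$fwd_steps) else NA_real_)
    })
    best <- NULL; best_d <- Inf
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      g <- info[[j]]$f0 - info[[i]]$f1 - 1
      if (g < 0 || g > params$max_gap_frames) next
      ## without a heading there is no basis for extrapolation: the
      ## segment is treated as paused and the rejoin radius is not
      ## scaled up with the gap length
      has_heading <- !is.null(info[[i]]$heading) && !is.na(info[[i]]$mstep)
      ext <- if (has_heading) {
        h <- info[[i]]$heading / sqrt(sum(info[[i]]$heading^2))
        info[[i]]$p1 + h * info[[i]]$mstep * (g + 1)
      } else info[[i]]$p1
      d <- sqrt(sum((info[[j]]$p0 - ext)^2))
      rad <- params$search_radius_px[2] * if (has_heading) max(g, 1) else 1
      if (d > rad || d >= best_d) next
      if (g >= 1L) {
        pts <- rbind(segs[[i]]$points, segs[[j]]$points)
        if (points_are_consistent(pts, params)) {
          best_d <- d; best <- list(i = i, j = j, pts = pts)
        }
      } else {
        ## abutting segments: try dropping the junction outlier point
        pa <- segs[[i]]$points; pb <- segs[[j]]$points
        variants <- list()
        if (nrow(pa) > 1L)
          variants <- c(variants, list(rbind(pa[-nrow(pa), , drop = FALSE], pb)))
        if (nrow(pb) > 1L)
          variants <- c(variants, list(rbind(pa, pb[-1L, , drop = FALSE])))
        for (pts in variants) {
          if (points_are_consistent(pts, params)) {
            best_d <- d; best <- list(i = i, j = j, pts = pts)
            break
          }
        }
      }
    }
    if (is.null(best)) return(segs)
    a <- segs[[best$i]]; bseg <- segs[[best$j]]
    a$points <- best$pts
    a$heading <- bseg$heading %||% a$heading
    a$fwd_steps <- c(a$fwd_steps, bseg$fwd_steps)
    segs[[best$i]] <- a
    segs <- segs[-best$j]
  }
}

## A merge is accepted only if the joined point sequence still passes the
## independent per-step constraint checker (the junction can retroactively
## violate the angle gates even when the extrapolation bound holds).
points_are_consistent <- function(pts, params) {
  tr <- list(points = data.frame(frame = pts[, 1], x = pts[, 2],
                                 y = pts[, 3]))
  isTRUE(validate_tracks(list(tr), within_params(params)))
}

## relax only the min-length requirement while checking merges
within_params <- function(params) {
  p <- params
  p$min_track_frames <- 2L
  p
}

#' Independent post-hoc constraint checker for tracks
#'
#' Re-derives the feasibility of every emitted track directly from its
#' stored points: strictly increasing frames, minimum observed length,
#' gap bound, step-length and angle gates, and the gap-closing
#' extrapolation bound.
#'
#' @param tracks list of `plusend_track`s from [link_tracks()].
#' @param params the [tracking_params()] used for linking.
#' @return `TRUE` when all constraints hold, otherwise a character vector
#'   describing the violations.
#' @export
validate_tracks <- function(tracks, params) {
  bad <- character()
  for (k in seq_along(tracks)) {
    p <- tracks[[k]]$points
    f <- p$frame
    if (is.unsorted(f, strictly = TRUE))
      bad <- c(bad, sprintf("track %d: frames not strictly increasing", k))
    if (nrow(p) < params$min_track_frames)
      bad <- c(bad, sprintf("track %d: only %d observed points", k, nrow(p)))
    heading <- NULL; fwd <- numeric()
    for (i in seq_len(nrow(p) - 1L)) {
      df <- f[i + 1L] - f[i]
      step <- c(p$x[i + 1L] - p$x[i], p$y[i + 1L] - p$y[i])
      d <- sqrt(sum(step^2))
      if (df == 1L) {
        kind <- classify_step(step, heading, if (length(fwd)) mean(fwd)
                              else NA_real_, params)
        if (is.na(kind))
          bad <- c(bad, sprintf("track %d: infeasible step at frame %d",
                                k, f[i]))
        if (identical(kind, "forward") && d > params$fluctuation_radius_px) {
          heading <- step; fwd <- c(fwd, d)
        }
      } else {
        g <- df - 1L
        if (g > params$max_gap_frames)
          bad <- c(bad, sprintf("track %d: gap of %d frames at frame %d",
                                k, g, f[i]))
        has_heading <- !is.null(heading) && length(fwd) > 0
        ext <- if (has_heading) {
          h <- heading / sqrt(sum(heading^2))
          c(p$x[i], p$y[i]) + h * mean(fwd) * df
        } else c(p$x[i], p$y[i])
        dd <- sqrt(sum((c(p$x[i + 1L], p$y[i + 1L]) - ext)^2))
        if (dd > params$search_radius_px[2] * (if (has_heading) g else 1))
          bad <- c(bad, sprintf("track %d: gap jump %.1f px exceeds %g px",
                                k, dd, params$search_radius_px[2] * g))
      }
    }
  }
  if (length(bad)) bad else TRUE
}

#' Per-movie track summary
#'
#' Velocity is the least-squares slope of the cumulative arclength along
#' the track's own path against time; lifetime is
#' `(last - first frame) * frame_interval_s`.
#'
#' @param tracks list of `plusend_track`s.
#' @param pixel_size_um pixel size in um.
#' @param params the [tracking_params()] (for the frame interval).
#' @return List with `n_tracks`, `median_velocity_um_s`,
#'   `median_lifetime_s` and `per_track` (data.frame).
#' @export
track_summary <- function(tracks, pixel_size_um, params = tracking_params()) {
  check_pixel_size(pixel_size_um)
  if (length(tracks) == 0L)
    return(list(n_tracks = 0L, median_velocity_um_s = NA_real_,
                median_lifetime_s = NA_real_,
                per_track = data.frame(velocity_um_s = numeric(),
                                       lifetime_s = numeric())))
  dt <- params$frame_interval_s
  per <- t(vapply(tracks, function(tr) {
    p <- tr$points
    d_um <- c(0, cumsum(sqrt(diff(p$x)^2 + diff(p$y)^2))) * pixel_size_um
    tt <- (p$frame - p$frame[1]) * dt
    v <- unname(coef(lm(d_um ~ tt))[2])
    c(v, (max(p$frame) - min(p$frame)) * dt)
  }, numeric(2)))
  list(n_tracks = length(tracks),
       median_velocity_um_s = median(per[, 1]),
       median_lifetime_s = median(per[, 2]),
       per_track = data.frame(velocity_um_s = per[, 1],
                              lifetime_s = per[, 2]))
}

## ---- assignment solver ----------------------------------------------------

## Minimum-cost square assignment (shortest augmenting path / Hungarian
## with potentials, O(n^3)). Returns, for each row, the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)   # index 1 = virtual col 0
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}
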