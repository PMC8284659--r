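## Kymograph construction and trajectory extraction. A kymograph is an
## S x T image: arclength along the trace (1 px steps) against frame
## number; a comet moving at constant velocity appears as a sloped ridge.

#' Build a kymograph from a time-lapse stack
#'
#' For every frame the stack is sampled along the trace at 1-pixel
#' arclength steps (bilinear interpolation) and averaged across a
#' perpendicular band `band_px` wide; column t of the kymograph is that
#' profile.
#'
#' @param movie a [movie_stack()].
#' @param trace an [axon_trace()].
#' @param band_px odd band width in pixels.
#' @return A `kymograph`: list with `values` (S x T matrix),
#'   `arclength_step_um`, `frame_interval_s`.
#' @export
build_kymograph <- function(movie, trace, band_px = 3L) {
  stopifnot(inherits(movie, "movie_stack"), inherits(trace, "axon_trace"))
  Tn <- dim(movie$frames)[1]
  cols <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    img <- image2d(movie$frames[t, , ], movie$pixel_size_um)
    cols[[t]] <- trace_profile(img, trace, band_px)$intensity
  }
  values <- do.call(cbind, cols)
  structure(list(values = values,
                 arclength_step_um = movie$pixel_size_um,
                 frame_interval_s = movie$frame_interval_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d positions x %d frames (step %.4g um, dt %g s)\n",
              nrow(x$values), ncol(x$values), x$arclength_step_um,
              x$frame_interval_s))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(
    x = (seq_len(ncol(x$values)) - 1) * x$frame_interval_s,
    y = (seq_len(nrow(x$values)) - 1) * x$arclength_step_um,
    z = t(x$values), xlab = "time (s)", ylab = "arclength (um)",
    col = grDevices::gray.colors(256), useRaster = TRUE, ...)
  invisible(x)
}

#' Extract comet trajectories from a kymograph
#'
#' Per-column peaks (same DoG + robust-threshold rule as the still-image
#' detector) are linked greedily frame to frame within `max_step_um`
#' (scaled by the gap length when frames are missed), with gap closing up
#' to `max_gap_frames`; ties are broken by the smallest spatial jump.
#' Tracks with fewer than `min_track_frames` observed points are
#' discarded. Velocity is the least-squares slope of arclength against
#' time; lifetime is `(last_frame - first_frame) * frame_interval_s`
#' (gaps count).
#'
#' @param kymo a `kymograph`.
#' @param psf_sigma_um PSF sigma used for the DoG scales.
#' @param k_mad detection threshold in robust noise sds.
#' @param min_sep_um minimum peak separation within a column.
#' @param max_step_um maximum frame-to-frame displacement; default twice
#'   the displacement of a 0.5 um/s comet per frame.
#' @param max_gap_frames maximum number of missed frames bridged.
#' @param min_track_frames minimum observed points per track.
#' @param background fixed background for detection; `NULL` to estimate
#'   per column.
#' @return List of `kymo_track` objects: `points` (data.frame `frame`,
#'   `arclength_um`; frame is 1-based), `velocity_um_s`, `lifetime_s`.
#' @export
extract_tracks <- function(kymo, psf_sigma_um = 0.15, k_mad = 5,
                           min_sep_um = 1, max_step_um = NULL,
                           max_gap_frames = 2L, min_track_frames = 3L,
                           background = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  dt <- kymo$frame_interval_s
  if (is.null(max_step_um)) max_step_um <- 2 * 0.5 * dt
  Tn <- ncol(kymo$values)
  s_um <- (seq_len(nrow(kymo$values)) - 1) * kymo$arclength_step_um
  peaks <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    prof <- intensity_profile(s_um, kymo$values[, t])
    bg <- background %||% median(prof$intensity)
    peaks[[t]] <- find_profile_peaks(prof, psf_sigma_um, k_mad, min_sep_um, bg)
  }
  link_kymo_peaks(peaks, dt, max_step_um, max_gap_frames, min_track_frames)
}

link_kymo_peaks <- function(peaks, dt, max_step_um, max_gap_frames,
                            min_track_frames) {
  active <- list()   # each: list(frames, pos)
  done <- list()
  for (t in seq_along(peaks)) {
    ps <- peaks[[t]]
    ## retire tracks whose gap would exceed the bound
    if (length(active)) {
      last <- vapply(active, function(a) a$frames[length(a$frames)], 0)
      retire <- t - last - 1 > max_gap_frames
      done <- c(done, active[retire])
      active <- active[!retire]
    }
    if (length(ps) && length(active)) {
      last_pos <- vapply(active, function(a) a$pos[length(a$pos)], 0)
      last_frm <- vapply(active, function(a) a$frames[length(a$frames)], 0)
      cand <- expand.grid(trk = seq_along(active), pk = seq_along(ps))
      cand$d <- abs(last_pos[cand$trk] - ps[cand$pk])
      cand$lim <- max_step_um * (t - last_frm[cand$trk])
      cand <- cand[cand$d <= cand$lim, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      used_t <- logical(length(active)); used_p <- logical(length(ps))
      for (r in seq_len(nrow(cand))) {
        i <- cand$trk[r]; j <- cand$pk[r]
        if (used_t[i] || used_p[j]) next
        used_t[i] <- TRUE; used_p[j] <- TRUE
        active[[i]]$frames <- c(active[[i]]$frames, t)
        active[[i]]$pos <- c(active[[i]]$pos, ps[j])
      }
      for (j in which(!used_p))
        active[[length(active) + 1L]] <- list(frames = t, pos = ps[j])
    } else if (length(ps)) {
      for (j in seq_along(ps))
        active[[length(active) + 1L]] <- list(frames = t, pos = ps[j])
    }
  }
  done <- c(done, active)
  done <- Filter(function(a) length(a$frames) >= min_track_frames, done)
  lapply(done, function(a) {
    tt <- (a$frames - 1) * dt
    vel <- unname(coef(lm(a$pos ~ tt))[2])
    structure(list(points = data.frame(frame = a$frames,
                                       arclength_um = a$pos),
                   velocity_um_s = vel,
                   lifetime_s = (max(a$frames) - min(a$frames)) * dt),
              class = "kymo_track")
  })
}

#' @export
print.kymo_track <- function(x, ...) {
  cat(sprintf("<kymo_track> %d points, v = %.3f um/s, lifetime %g s\n",
              nrow(x$points), x$velocity_um_s, x$lifetime_s))
  invisible(x)
}

#' Per-neuron summary of comet dynamics
#'
#' @param tracks list of `kymo_track` objects.
#' @return List with `n_tracks`, `median_velocity_um_s`,
#'   `median_lifetime_s` (`NA` and `degenerate = TRUE` when empty).
#' @export
comet_dynamics_summary <- function(tracks) {
  if (length(tracks) == 0L)
    return(list(n_tracks = 0L, median_velocity_um_s = NA_real_,
                median_lifetime_s = NA_real_, degenerate = TRUE))
  list(n_tracks = length(tracks),
       median_velocity_um_s = median(vapply(tracks, `[[`, 0, "velocity_um_s")),
       median_lifetime_s = median(vapply(tracks, `[[`, 0, "lifetime_s")),
       degenerate = FALSE)
}

#' Match extracted kymograph tracks to simulation ground truth
#'
#' For each ground-truth comet with at least `min_frames` frames of life
#' inside the movie, the best extracted track is the one with the
#' smallest median position error over temporally overlapping frames
#' (overlap of at least half the shorter lifespan required); it is a
#' match when that error is below `tol_um`. Each extracted track is used
#' at most once.
#'
#' @param truth ground-truth data.frame from [simulate_comet_movie()].
#' @param tracks list of `kymo_track`s from [extract_tracks()].
#' @param frame_interval_s frame interval of the movie.
#' @param n_frames number of movie frames.
#' @param tol_um matching tolerance on the median position error.
#' @param min_frames minimum truth frames for a matchable comet.
#' @return data.frame with one row per matchable truth comet: `truth_id`,
#'   `track_id` (NA if unmatched), true and estimated velocity and
#'   lifetime.
#' @export
match_kymo_tracks <- function(truth, tracks, frame_interval_s, n_frames,
                              tol_um = 1, min_frames = 3L) {
  dt <- frame_interval_s
  frame_times <- (seq_len(n_frames) - 1) * dt
  matchable <- which(vapply(seq_len(nrow(truth)), function(i) {
    sum(frame_times >= truth$birth_time_s[i] &
        frame_times < truth$death_time_s[i]) >= min_frames
  }, TRUE))
  out <- data.frame(truth_id = matchable, track_id = NA_integer_,
                    v_true = truth$velocity_um_s[matchable],
                    v_est = NA_real_,
                    lifetime_true = NA_real_,
                    lifetime_est = NA_real_)
  ## candidate (truth, track) pairs with overlap and error, then a
  ## globally greedy assignment on ascending error
  pairs <- list()
  for (r in seq_along(matchable)) {
    i <- matchable[r]
    tf <- which(frame_times >= truth$birth_time_s[i] &
                frame_times < truth$death_time_s[i])
    tp <- truth$birth_arclength_um[i] +
      truth$velocity_um_s[i] * (frame_times[tf] - truth$birth_time_s[i])
    out$lifetime_true[r] <- (max(tf) - min(tf)) * dt
    for (k in seq_along(tracks)) {
      pk <- tracks[[k]]$points
      ov <- intersect(tf, pk$frame)
      if (length(ov) < 0.5 * min(length(tf), nrow(pk))) next
      err <- median(abs(pk$arclength_um[match(ov, pk$frame)] -
                        tp[match(ov, tf)]))
      if (err <= tol_um)
        pairs[[length(pairs) + 1L]] <- c(r = r, k = k, err = err)
    }
  }
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, "err"]), , drop = FALSE]
    used_t <- logical(nrow(out)); used_k <- logical(length(tracks))
    for (q in seq_len(nrow(pm))) {
      r <- pm[q, "r"]; k <- pm[q, "k"]
      if (used_t[r] || used_k[k]) next
      used_t[r] <- TRUE; used_k[k] <- TRUE
      out$track_id[r] <- k
      out$v_est[r] <- tracks[[k]]$velocity_um_s
      out$lifetime_est[r] <- tracks[[k]]$lifetime_s
    }
  }
  out
}
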