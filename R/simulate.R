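## Synthetic fluorescence generator: axon traces with optional curled
## segments, EB-comet movies and stills with known ground truth.

#' Simulate a traced axon, optionally with curled segments
#'
#' Produces a polyline trace of total arclength `axon_length_um` laid out
#' horizontally in the image, the soma end at low x. Each curl
#' specification inserts a closed loop whose enclosed polygon has the
#' requested area; the loop's perimeter is carved out of the arclength
#' budget so the total arclength is preserved exactly.
#'
#' @param config a [sim_config()].
#' @param curl_specs list of `c(arclength_um, target_area_um2)` pairs: the
#'   loop is centred at that arclength and encloses that area. Spans must
#'   be disjoint and inside `[0, axon_length_um]`.
#' @param loop_n number of vertices used for each loop polygon.
#' @return A list with elements `trace` (an [axon_trace()]) and `curls`
#'   (a list of ground-truth records with `polygon_px`, `area_um2`,
#'   `arclength_span_um`).
#' @export
simulate_axon_trace <- function(config, curl_specs = list(), loop_n = 72L) {
  stopifnot(inherits(config, "sim_config"))
  px <- config$pixel_size_um
  L <- config$axon_length_um
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  y0 <- floor(rows * 0.6)

  specs <- lapply(curl_specs, function(s) {
    s <- as.numeric(s)
    if (length(s) != 2L || s[2] <= 0)
      stop("curl_specs entries must be c(arclength_um, target_area_um2 > 0)")
    ## radius such that the loop_n-gon area is exactly the target
    r_um <- sqrt(2 * s[2] / (loop_n * sin(2 * pi / loop_n)))
    per_um <- 2 * loop_n * r_um * sin(pi / loop_n)
    list(center = s[1], area = s[2], r_um = r_um, per_um = per_um,
         span = c(s[1] - per_um / 2, s[1] + per_um / 2))
  })
  if (length(specs) > 1L) {
    o <- order(vapply(specs, function(s) s$center, 0))
    specs <- specs[o]
    for (i in seq_len(length(specs) - 1L))
      if (specs[[i]]$span[2] > specs[[i + 1L]]$span[1])
        stop("curl spans overlap: spans centred at ",
             specs[[i]]$center, " and ", specs[[i + 1L]]$center, " um")
  }
  for (s in specs)
    if (s$span[1] < 0 || s$span[2] > L)
      stop(sprintf("curl span [%.2f, %.2f] um outside axon [0, %g] um",
                   s$span[1], s$span[2], L))
  for (s in specs)
    if (y0 - 2 * s$r_um / px < 5)
      stop(sprintf(paste0("curl at %.2f um (radius %.2f um) does not fit ",
                          "the image with a 5 px margin"),
                   s$center, s$r_um))

  x <- 5           # soma end, 5 px margin
  verts <- matrix(c(x, y0), 1L)
  s_done <- 0      # arclength already laid out (um)
  curls <- list()
  for (s in specs) {
    dx <- (s$span[1] - s_done) / px
    if (dx > 0) {
      x <- x + dx
      verts <- rbind(verts, c(x, y0))
    }
    r_px <- s$r_um / px
    th <- 2 * pi * seq_len(loop_n - 1L) / loop_n
    loop <- cbind(x + r_px * sin(th), (y0 - r_px) + r_px * cos(th))
    poly <- rbind(c(x, y0), loop)          # closed implicitly
    verts <- rbind(verts, loop, c(x, y0))  # return to the anchor point
    area_px <- shoelace_area(poly)
    curls[[length(curls) + 1L]] <-
      list(polygon_px = poly, area_um2 = area_px * px^2,
           arclength_span_um = s$span)
    s_done <- s$span[2]
  }
  dx <- (L - s_done) / px
  if (dx > 0) {
    x <- x + dx
    verts <- rbind(verts, c(x, y0))
  }
  if (x > cols - 1 - 5)
    stop("axon does not fit the image width with a 5 px margin")
  list(trace = axon_trace(verts, px), curls = curls)
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

## ---- rendering core -------------------------------------------------------

## Intrinsic comet emission profile along the trace; d = arclength - tip
## (um), oriented so that d > 0 is ahead of the tip (direction of
## motion): a short Gaussian leading edge of fixed width and an
## exponential trailing tail. The front width is a property of the comet,
## deliberately independent of the PSF, so the total emitted flux does
## not change when the optics do; the rendered leading edge is this front
## convolved with the PSF.
COMET_FRONT_SIGMA_UM <- 0.1

comet_profile <- function(d, sigma_um, tail_um) {
  ifelse(d > 0, exp(-d^2 / (2 * COMET_FRONT_SIGMA_UM^2)), exp(d / tail_um))
}

## Deposit line-integrated intensity onto a q-times oversampled grid,
## blur with the PSF, and integrate back to sensor pixels (block sum).
## `deposits` is a list of data.frames with columns s_px (arclength in px)
## and w (deposit weight); a deposit may carry its own `trace` attribute,
## otherwise `trace` is used.
render_core <- function(trace, deposits, config, q = 3L) {
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  px <- config$pixel_size_um
  sub <- matrix(0, rows * q, cols * q)
  any_dep <- FALSE
  for (d in deposits) {
    if (nrow(d) == 0L) next
    tr <- attr(d, "trace") %||% trace
    pt <- trace_point_at(tr, d$s_px)$xy
    ic <- floor((pt[, 1] + 0.5) * q) + 1L   # sub-col from x
    ir <- floor((pt[, 2] + 0.5) * q) + 1L   # sub-row from y
    keep <- ir >= 1L & ir <= rows * q & ic >= 1L & ic <= cols * q
    if (!all(keep)) { ir <- ir[keep]; ic <- ic[keep]; d <- d[keep, , drop = FALSE] }
    if (nrow(d) == 0L) next
    idx <- (ic - 1L) * (rows * q) + ir
    ag <- rowsum(d$w, idx)
    sub[as.integer(rownames(ag))] <- sub[as.integer(rownames(ag))] + ag[, 1]
    any_dep <- TRUE
  }
  if (any_dep && any(sub != 0)) {
    sigma_sub <- config$psf_sigma_um / (px / q)
    ## blur only the strip of rows/cols actually carrying deposits
    nz <- which(sub != 0, arr.ind = TRUE)
    pad <- ceiling(4 * sigma_sub) + q
    r0 <- max(1L, min(nz[, 1]) - pad); r1 <- min(nrow(sub), max(nz[, 1]) + pad)
    c0 <- max(1L, min(nz[, 2]) - pad); c1 <- min(ncol(sub), max(nz[, 2]) + pad)
    sub[r0:r1, c0:c1] <- EBImage::gblur(sub[r0:r1, c0:c1, drop = FALSE],
                                        sigma = sigma_sub)
  }
  block_sum(sub, q)
}

block_sum <- function(m, q) {
  R <- nrow(m) %/% q; C <- ncol(m) %/% q
  m <- rowsum(m, rep(seq_len(R), each = q))
  t(rowsum(t(m), rep(seq_len(C), each = q)))
}

## Deposit samples for one comet with tip at `tip_um` along the trace.
## tail_side = -1: tail at lower arclength (anterograde comet).
## Pixel values follow the field convention: a pixel holds the blurred
## emission field at its footprint, independent of the pixel size, so
## measurements are comparable across resolutions; the summed
## background-subtracted image times px^2 is the comet's emitted flux,
## independent of the PSF width.
comet_deposit <- function(tip_um, amplitude, config, tail_side, L_um,
                          tail_um = config$comet_tail_length_um, q = 3L) {
  px <- config$pixel_size_um
  step_um <- px / (2 * q)
  sig <- config$psf_sigma_um
  fr <- 4 * COMET_FRONT_SIGMA_UM
  lo <- tip_um - if (tail_side < 0) 7 * tail_um else fr
  hi <- tip_um + if (tail_side < 0) fr else 7 * tail_um
  s <- seq(max(0, lo), min(L_um, hi), by = step_um)
  if (length(s) == 0L) return(data.frame(s_px = numeric(), w = numeric()))
  d <- (s - tip_um) * (-tail_side)   # >0 ahead of the tip
  data.frame(s_px = s / px,
             w = amplitude * comet_profile(d, sig, tail_um) *
               (step_um / px) / px)
}

lattice_deposit <- function(config, L_um, q = 3L) {
  px <- config$pixel_size_um
  step_um <- px / (2 * q)
  s <- seq(0, L_um, by = step_um)
  w <- config$lattice_intensity * sqrt(2 * pi) *
    (config$psf_sigma_um / px) * (step_um / px)
  data.frame(s_px = s / px, w = rep(w, length(s)))
}

apply_noise <- function(img, config) {
  if (config$poisson_noise) {
    img[] <- rpois(length(img), lambda = pmax(img, 0))
  }
  if (config$gaussian_noise_sd > 0) {
    img <- img + rnorm(length(img), sd = config$gaussian_noise_sd)
  }
  img
}

## ---- movies and stills ----------------------------------------------------

#' Simulate a comet time-lapse movie with ground truth
#'
#' Comets nucleate along the axon as a homogeneous Poisson process at
#' `comet_nucleation_rate_per_um_min`, advance at `comet_velocity_um_s`
#' and die after exponentially distributed lifetimes (or on leaving the
#' axon). Each comet is rendered as a Gaussian leading edge with an
#' exponential trailing tail (tail towards the soma for anterograde
#' comets), blurred by the PSF; lattice fluorescence is painted along the
#' trace; the camera offset, optional Poisson shot noise and Gaussian read
#' noise are applied last. Identical configurations (including
#' `rng_seed`) give bit-identical output.
#'
#' @param trace an [axon_trace()], e.g. from [simulate_axon_trace()].
#' @param config a [sim_config()].
#' @return A list with `movie` (a [movie_stack()]) and `truth`, a
#'   data.frame with one row per comet: `birth_time_s`, `death_time_s`,
#'   `birth_arclength_um`, `velocity_um_s`, `amplitude`,
#'   `tail_length_um`.
#' @export
simulate_comet_movie <- function(trace, config) {
  stopifnot(inherits(trace, "axon_trace"), inherits(config, "sim_config"))
  if (config$n_frames < 2L) stop("n_frames must be >= 2 for a movie")
  L <- trace_arclength_um(trace)
  dt <- config$frame_interval_s
  T_total <- (config$n_frames - 1) * dt
  v <- config$comet_velocity_um_s

  with_seed(config$rng_seed, {
    n <- rpois(1L, config$comet_nucleation_rate_per_um_min * L * T_total / 60)
    truth <- data.frame(
      birth_time_s = sort(runif(n, 0, T_total)),
      birth_arclength_um = runif(n, 0, L))
    life <- rexp(n, rate = 1 / config$comet_lifetime_mean_s)
    exit <- if (v > 0) (L - truth$birth_arclength_um) / v
            else if (v < 0) truth$birth_arclength_um / abs(v)
            else rep(Inf, n)
    truth$death_time_s <- truth$birth_time_s + pmin(life, exit)
    truth$velocity_um_s <- rep(v, n)
    truth$amplitude <- rep(config$comet_amplitude, n)
    truth$tail_length_um <- rep(config$comet_tail_length_um, n)

    frames <- array(0, c(config$n_frames, config$image_shape[1],
                         config$image_shape[2]))
    lat <- lattice_deposit(config, L)
    tail_side <- if (v < 0) 1 else -1
    for (k in seq_len(config$n_frames)) {
      t_k <- (k - 1) * dt
      alive <- which(truth$birth_time_s <= t_k & t_k < truth$death_time_s)
      deps <- list(lat)
      for (i in alive) {
        tip <- truth$birth_arclength_um[i] + v * (t_k - truth$birth_time_s[i])
        deps[[length(deps) + 1L]] <-
          comet_deposit(tip, truth$amplitude[i], config, tail_side, L,
                        tail_um = truth$tail_length_um[i])
      }
      img <- render_core(trace, deps, config) + config$bg_offset
      frames[k, , ] <- apply_noise(img, config)
    }
    list(movie = movie_stack(frames, config$pixel_size_um, dt), truth = truth)
  })
}

#' Render a single frame at a given time
#'
#' Deterministic rendering of the scene at time `t_s`; noise is off by
#' default so the output can serve as an exact fixture.
#'
#' @param trace an [axon_trace()].
#' @param comets ground-truth data.frame as produced by
#'   [simulate_comet_movie()] (may have zero rows).
#' @param t_s time in seconds, within the movie duration.
#' @param config a [sim_config()].
#' @param noise apply the configured noise model (uses the session RNG).
#' @return An [image2d()].
#' @export
render_still <- function(trace, comets, t_s, config, noise = FALSE) {
  stopifnot(inherits(trace, "axon_trace"), inherits(config, "sim_config"))
  T_total <- (config$n_frames - 1) * config$frame_interval_s
  if (t_s < 0 || t_s > T_total)
    stop("t_s outside the movie duration [0, ", T_total, "] s")
  L <- trace_arclength_um(trace)
  deps <- list()
  if (config$lattice_intensity > 0) deps <- list(lattice_deposit(config, L))
  if (nrow(comets) > 0) {
    alive <- which(comets$birth_time_s <= t_s & t_s < comets$death_time_s)
    for (i in alive) {
      v <- comets$velocity_um_s[i]
      tip <- comets$birth_arclength_um[i] + v * (t_s - comets$birth_time_s[i])
      if (tip < 0 || tip > L)
        stop(sprintf("comet %d at %.2f um is outside the trace [0, %.2f] um",
                     i, tip, L))
      tail_side <- if (v < 0) 1 else -1
      deps[[length(deps) + 1L]] <-
        comet_deposit(tip, comets$amplitude[i], config, tail_side, L,
                      tail_um = comets$tail_length_um[i])
    }
  }
  img <- render_core(trace, deps, config) + config$bg_offset
  if (noise) img <- apply_noise(img, config)
  image2d(img, config$pixel_size_um)
}

#' Comet amplitude giving a target peak signal-to-noise ratio
#'
#' Renders one comet noiselessly, measures its peak intensity above the
#' local comet-free image, and scales the configured amplitude so the peak
#' equals `snr` times the expected noise sd at background level
#' (Gaussian read noise plus, if enabled, shot noise of offset+lattice).
#'
#' @param config a [sim_config()].
#' @param snr target peak signal-to-noise ratio.
#' @return The amplitude (same units as `comet_amplitude`).
#' @export
amplitude_for_snr <- function(config, snr = 5) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_axon_trace(config)
  one <- data.frame(birth_time_s = 0, birth_arclength_um = config$axon_length_um / 2,
                    death_time_s = 1e9, velocity_um_s = 0,
                    amplitude = config$comet_amplitude,
                    tail_length_um = config$comet_tail_length_um)
  with_c <- render_still(sim$trace, one, 0, config)$pixels
  without <- render_still(sim$trace, one[0, ], 0, config)$pixels
  peak_per_amp <- max(with_c - without) / config$comet_amplitude
  noise_sd <- sqrt(config$gaussian_noise_sd^2 +
                   if (config$poisson_noise)
                     config$bg_offset + config$lattice_intensity else 0)
  if (noise_sd == 0) stop("configuration has no noise; SNR is undefined")
  snr * noise_sd / peak_per_amp
}

## ---- 2D tracking benchmark ------------------------------------------------

#' Simulate a 2D field of moving comets with ground truth
#'
#' Renders `n_tracks` straight-moving comets with random directions and
#' speeds in an open field (no axon lattice), for benchmarking the 2D
#' particle tracker. Comets appear at a random frame, live an
#' exponentially distributed time and keep a constant heading.
#'
#' @param config a [sim_config()]; `image_shape`, `frame_interval_s`,
#'   `n_frames`, PSF, amplitude, tail and noise fields are used.
#' @param n_tracks number of comets.
#' @param speed_range_um_s range from which each comet's speed is drawn.
#' @param min_gap_px minimum distance between concurrent comets in any
#'   shared frame; comets closer than about a comet length are optically
#'   merged and cannot be scored by any tracker.
#' @param seed RNG seed (falls back to `config$rng_seed`).
#' @return List with `movie` (a [movie_stack()]) and `truth`, a list with
#'   one data.frame per comet (`frame`, `x`, `y` in px) plus a
#'   `speed_um_s` attribute.
#' @export
simulate_tracking_movie <- function(config, n_tracks = 10,
                                    speed_range_um_s = c(0.35, 0.55),
                                    min_gap_px = 15, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$rng_seed
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  px <- config$pixel_size_um; dt <- config$frame_interval_s
  Tn <- config$n_frames
  mar <- 15
  with_seed(seed, {
    truth <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      speed <- runif(1, speed_range_um_s[1], speed_range_um_s[2])
      b <- sample.int(max(1L, Tn %/% 3L), 1L)
      ## cap the lifetime so the straight path fits inside the margins
      max_fr <- floor((min(rows, cols) - 1 - 2 * mar) * px * 0.7 /
                      (speed * dt))
      life_fr <- min(max_fr,
                     max(3L, ceiling(rexp(1, 1 / config$comet_lifetime_mean_s) / dt)))
      d <- min(Tn, b + life_fr)
      ok <- FALSE
      for (try in 1:500) {
        th <- runif(1, 0, 2 * pi)
        start <- c(runif(1, mar, cols - 1 - mar), runif(1, mar, rows - 1 - mar))
        end <- start + c(cos(th), sin(th)) * speed * (d - b) * dt / px
        if (!(all(end >= mar) && end[1] <= cols - 1 - mar &&
              end[2] <= rows - 1 - mar)) next
        fr <- b:d
        pos <- cbind(start[1] + cos(th) * speed * (fr - b) * dt / px,
                     start[2] + sin(th) * speed * (fr - b) * dt / px)
        clear <- TRUE
        for (prev in truth) {
          if (is.null(prev)) next
          cf <- intersect(fr, prev$frame)
          if (!length(cf)) next
          dd <- sqrt((pos[match(cf, fr), 1] - prev$x[match(cf, prev$frame)])^2 +
                     (pos[match(cf, fr), 2] - prev$y[match(cf, prev$frame)])^2)
          if (min(dd) < min_gap_px) { clear <- FALSE; break }
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place comet ", i, " inside the image")
      df <- data.frame(frame = fr, x = pos[, 1], y = pos[, 2])
      attr(df, "speed_um_s") <- speed
      attr(df, "theta") <- th
      truth[[i]] <- df
    }
    frames <- array(0, c(Tn, rows, cols))
    for (t in seq_len(Tn)) {
      deps <- list()
      for (i in seq_len(n_tracks)) {
        df <- truth[[i]]
        r <- match(t, df$frame)
        if (is.na(r)) next
        th <- attr(df, "theta")
        ## straight path-aligned trace long enough to hold the profile
        ext <- (6 * config$comet_tail_length_um + 4 * config$psf_sigma_um) / px
        p0 <- c(df$x[r], df$y[r]) - c(cos(th), sin(th)) * ext
        p1 <- c(df$x[r], df$y[r]) + c(cos(th), sin(th)) * ext
        tr <- axon_trace(rbind(p0, p1), px)
        dep <- comet_deposit(ext * px, config$comet_amplitude, config,
                             tail_side = -1, L_um = 2 * ext * px)
        attr(dep, "trace") <- tr
        deps[[length(deps) + 1L]] <- dep
      }
      img <- render_core(NULL, deps, config) + config$bg_offset
      frames[t, , ] <- apply_noise(img, config)
    }
    list(movie = movie_stack(frames, px, dt), truth = truth)
  })
}

#' Match 2D tracks to ground truth
#'
#' A truth comet is matched by the (unused) extracted track that covers
#' the largest fraction of its frames within `tol_px`; it counts as
#' recovered when at least half of its frames are covered.
#'
#' @param truth list of per-comet data.frames from
#'   [simulate_tracking_movie()].
#' @param tracks list of `plusend_track`s from [link_tracks()].
#' @param tol_px spatial tolerance in pixels.
#' @return data.frame with `truth_id`, `track_id` (NA if unmatched),
#'   `frac_covered`, `speed_true_um_s`.
#' @export
match_tracks_2d <- function(truth, tracks, tol_px = 2) {
  out <- data.frame(truth_id = seq_along(truth), track_id = NA_integer_,
                    frac_covered = 0,
                    speed_true_um_s = vapply(truth, attr, 0, "speed_um_s"))
  pairs <- list()
  for (i in seq_along(truth)) {
    df <- truth[[i]]
    for (k in seq_along(tracks)) {
      p <- tracks[[k]]$points
      ov <- match(df$frame, p$frame)
      hit <- !is.na(ov) &
        sqrt((p$x[ov] - df$x)^2 + (p$y[ov] - df$y)^2) <= tol_px
      frac <- sum(hit, na.rm = TRUE) / nrow(df)
      if (frac >= 0.5)
        pairs[[length(pairs) + 1L]] <- c(i = i, k = k, frac = frac)
    }
  }
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(-pm[, "frac"]), , drop = FALSE]
    used_t <- logical(length(truth)); used_k <- logical(length(tracks))
    for (q in seq_len(nrow(pm))) {
      i <- pm[q, "i"]; k <- pm[q, "k"]
      if (used_t[i] || used_k[k]) next
      used_t[i] <- TRUE; used_k[k] <- TRUE
      out$track_id[i] <- k
      out$frac_covered[i] <- pm[q, "frac"]
    }
  }
  out
}

#' Render a movie from a given comet ground-truth table
#'
#' Deterministic renderer used both by [simulate_comet_movie()]-style
#' pipelines and for controlled benchmark cohorts where the comet set is
#' constructed rather than drawn from the nucleation process.
#'
#' @param trace an [axon_trace()].
#' @param comets ground-truth data.frame (columns as in
#'   [simulate_comet_movie()]'s `truth`).
#' @param config a [sim_config()].
#' @param noise apply the configured noise model (under `rng_seed` when
#'   set).
#' @return A [movie_stack()].
#' @export
render_movie <- function(trace, comets, config, noise = TRUE) {
  stopifnot(inherits(trace, "axon_trace"), inherits(config, "sim_config"))
  L <- trace_arclength_um(trace)
  dt <- config$frame_interval_s
  frames <- array(0, c(config$n_frames, config$image_shape[1],
                       config$image_shape[2]))
  lat <- if (config$lattice_intensity > 0)
    list(lattice_deposit(config, L)) else list()
  with_seed(if (noise) config$rng_seed else NULL, {
    for (k in seq_len(config$n_frames)) {
      t_k <- (k - 1) * dt
      deps <- lat
      alive <- which(comets$birth_time_s <= t_k & t_k < comets$death_time_s)
      for (i in alive) {
        v <- comets$velocity_um_s[i]
        tip <- comets$birth_arclength_um[i] + v * (t_k - comets$birth_time_s[i])
        deps[[length(deps) + 1L]] <-
          comet_deposit(tip, comets$amplitude[i], config,
                        tail_side = if (v < 0) 1 else -1, L_um = L,
                        tail_um = comets$tail_length_um[i])
      }
      img <- render_core(trace, deps, config) + config$bg_offset
      frames[k, , ] <- if (noise) apply_noise(img, config) else img
    }
  })
  movie_stack(frames, config$pixel_size_um, dt)
}

#' Construct a resolvable benchmark comet cohort
#'
#' Draws `n` comets with the configured velocity whose trajectories never
#' come closer than `min_gap_um` to a temporally overlapping neighbour
#' (comets sharing a velocity keep a constant spacing), with lifetimes of
#' at least `min_frames` frames. Used to measure velocity and lifetime
#' recovery without confounding by optically unresolvable comet pairs.
#'
#' @param config a [sim_config()].
#' @param n number of comets.
#' @param min_gap_um minimum spacing between concurrent comets.
#' @param min_frames minimum lifetime in frames.
#' @param seed RNG seed (falls back to `config$rng_seed`).
#' @return Ground-truth data.frame as in [simulate_comet_movie()].
#' @export
benchmark_comets <- function(config, n = 20, min_gap_um = 1.5,
                             min_frames = 5L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$rng_seed
  L <- config$axon_length_um
  dt <- config$frame_interval_s
  T_total <- (config$n_frames - 1) * dt
  v <- config$comet_velocity_um_s
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:500) {
        b <- runif(1, 0, 0.6 * T_total)
        life <- max(min_frames * dt,
                    rexp(1, 1 / config$comet_lifetime_mean_s))
        p0 <- runif(1, 1, L - 1)
        exit <- if (v > 0) (L - p0) / v else if (v < 0) p0 / abs(v) else Inf
        d <- b + min(life, exit)
        if ((d - b) < min_frames * dt) next
        ok <- TRUE
        guard <- 3 * dt   # spatio-temporal guard band: a comet born just
                          # after another dies nearby is ambiguous for any
                          # scorer once gap closing can bridge the gap
        for (r in rows) {
          if (d + guard <= r$birth_time_s || b >= r$death_time_s + guard) next
          ## same velocity: spacing is the intercept difference
          gap <- abs((p0 - v * b) - (r$birth_arclength_um -
                                     v * r$birth_time_s))
          if (gap < min_gap_um) { ok <- FALSE; break }
        }
        if (ok) {
          rows[[length(rows) + 1L]] <- data.frame(
            birth_time_s = b, birth_arclength_um = p0, death_time_s = d,
            velocity_um_s = v, amplitude = config$comet_amplitude,
            tail_length_um = config$comet_tail_length_um)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("benchmark_comets: could not place comet ", i,
             " with the requested spacing")
    }
    do.call(rbind, rows)
  })
}
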