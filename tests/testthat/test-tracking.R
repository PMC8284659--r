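# Detections fixture: one data.frame per frame
det_frames <- function(frames, xs, ys = 20, Tn = max(frames)) {
  out <- replicate(Tn, data.frame(x = numeric(), y = numeric()),
                   simplify = FALSE)
  ys <- rep_len(ys, length(frames))
  for (i in seq_along(frames))
    out[[frames[i]]] <- rbind(out[[frames[i]]],
                              data.frame(x = xs[i], y = ys[i]))
  out
}

test_that("tracking parameter validation rejects nonsense", {
  expect_error(tracking_params(search_radius_px = c(12, 5)), "lower")
  expect_error(tracking_params(max_forward_angle_deg = 200), "0, 180")
  expect_error(tracking_params(min_track_frames = 1), ">= 2")
  expect_error(tracking_params(frame_interval_s = 0), "positive")
})

test_that("gap closing follows the printed gap and length bounds", {
  P <- tracking_params()
  ## frames 1-5, 8 missing frames, resume 14-18 colinear at 6 px/frame
  fr <- c(1:5, 14:18)
  trk <- link_tracks(det_frames(fr, 10 + 6 * (fr - 1)), P)
  expect_length(trk, 1)
  expect_equal(trk[[1]]$gap_frames, 8)

  ## 9 missing frames exceed the bound: two tracks
  fr2 <- c(1:5, 15:18)
  trk2 <- link_tracks(det_frames(fr2, 10 + 6 * (fr2 - 1)), P)
  expect_length(trk2, 2)

  ## a particle seen on only 2 frames yields no track
  trk3 <- link_tracks(det_frames(1:2, c(10, 16)), P)
  expect_length(trk3, 0)

  expect_true(isTRUE(validate_tracks(trk, P)))
  expect_true(isTRUE(validate_tracks(trk2, P)))
})

test_that("the independent checker catches constraint violations", {
  P <- tracking_params()
  bad <- list(structure(list(points = data.frame(
    frame = c(1, 2, 3), x = c(0, 6, 30), y = c(0, 0, 0)),
    gap_frames = 0), class = "plusend_track"))
  v <- validate_tracks(bad, P)
  expect_false(isTRUE(v))
  expect_match(v, "infeasible", all = FALSE)

  gap_bad <- list(structure(list(points = data.frame(
    frame = c(1, 2, 3, 14), x = c(0, 6, 12, 24), y = rep(0, 4)),
    gap_frames = 10), class = "plusend_track"))
  expect_match(validate_tracks(gap_bad, P), "gap", all = FALSE)
})

test_that("frame-to-frame assignment is a true minimum-cost assignment", {
  perms <- function(n) {
    if (n == 1) return(matrix(1L))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
  }
  set.seed(7)
  for (r in 1:50) {
    n <- sample(3:6, 1)
    C <- matrix(runif(n * n), n)
    if (r %% 2 == 0) C[sample(n * n, n)] <- 1e12
    a <- axonmt:::solve_assignment(C)
    expect_true(all(sort(a) == seq_len(n)))
    best <- min(apply(perms(n), 1, function(p) sum(C[cbind(seq_len(n), p)])))
    expect_equal(sum(C[cbind(seq_len(n), a)]), best, tolerance = 1e-9)
  }
})

## Exhaustive minimum-cost enumeration over all feasible link sets,
## written directly from the parameter semantics (independent of the
## implementation's data structures).
exhaustive_link_cost <- function(dets, P) {
  b <- P$search_radius_px[2]^2
  feasible <- function(chain, pt) {
    last <- chain$pos[[length(chain$pos)]]
    step <- pt - last
    d <- sqrt(sum(step^2))
    if (d > P$search_radius_px[2]) return(FALSE)
    if (d > P$fluctuation_radius_px && d < P$search_radius_px[1])
      return(FALSE)
    if (d > P$fluctuation_radius_px && !is.null(chain$heading)) {
      ang <- acos(max(-1, min(1, sum(step * chain$heading) /
                   (d * sqrt(sum(chain$heading^2)))))) * 180 / pi
      if (ang > P$max_forward_angle_deg &&
          !(ang >= 180 - P$max_backward_angle_deg && length(chain$fwd) &&
            d <= P$max_shrinkage_factor * mean(chain$fwd)))
        return(FALSE)
    }
    TRUE
  }
  extend <- function(chain, pt) {
    last <- chain$pos[[length(chain$pos)]]
    step <- pt - last
    d <- sqrt(sum(step^2))
    chain$pos <- c(chain$pos, list(pt))
    if (d > P$fluctuation_radius_px) {
      ang <- if (is.null(chain$heading)) 0 else
        acos(max(-1, min(1, sum(step * chain$heading) /
             (d * sqrt(sum(chain$heading^2)))))) * 180 / pi
      if (ang <= P$max_forward_angle_deg) {
        chain$heading <- step; chain$fwd <- c(chain$fwd, d)
      }
    }
    chain$len <- chain$len + 1L
    chain
  }
  ## enumerate matchings chain x detection per frame
  matchings <- function(chains, pts) {
    if (length(pts) == 0) return(list(list()))
    out <- list()
    rec <- function(pi, used, cur) {
      if (pi > length(pts)) { out[[length(out) + 1L]] <<- cur; return() }
      rec(pi + 1L, used, cur)            # detection starts a new chain
      for (ci in seq_along(chains)) {
        if (ci %in% used) next
        if (feasible(chains[[ci]], pts[[pi]]))
          rec(pi + 1L, c(used, ci), c(cur, list(c(ci, pi))))
      }
    }
    rec(1L, integer(), list())
    out
  }
  best <- Inf
  walk <- function(t, chains, cost) {
    if (cost >= best) return()
    if (t > length(dets)) { best <<- min(best, cost); return() }
    pts <- lapply(seq_len(nrow(dets[[t]])), function(i)
      c(dets[[t]]$x[i], dets[[t]]$y[i]))
    live <- which(vapply(chains, function(ch) ch$last == t - 1L, TRUE))
    for (mm in matchings(chains[live], pts)) {
      nch <- chains
      used_p <- integer()
      add <- 0
      for (lk in mm) {
        ci <- live[lk[1]]; pi <- lk[2]
        add <- add + sum((pts[[pi]] -
          nch[[ci]]$pos[[length(nch[[ci]]$pos)]])^2)
        nch[[ci]] <- extend(nch[[ci]], pts[[pi]])
        nch[[ci]]$last <- t
        used_p <- c(used_p, pi)
      }
      ## unmatched live chains and unmatched detections cost b each
      add <- add + b * (length(live) - length(mm))
      for (pi in setdiff(seq_along(pts), used_p)) {
        add <- add + b
        nch[[length(nch) + 1L]] <- list(pos = list(pts[[pi]]),
          heading = NULL, fwd = numeric(), len = 1L, last = t)
      }
      walk(t + 1L, nch, cost + add)
    }
  }
  walk(1L, list(), 0)
  best
}

## Realised cost of the linker's own frame-to-frame pass
linker_cost <- function(dets, trk, P) {
  b <- P$search_radius_px[2]^2
  cost <- 0
  n_det <- sum(vapply(dets, nrow, 0L))
  n_linked <- 0
  for (tr in trk) {
    p <- tr$points
    for (i in seq_len(nrow(p) - 1L)) {
      if (p$frame[i + 1L] - p$frame[i] == 1L) {
        cost <- cost + (p$x[i + 1L] - p$x[i])^2 + (p$y[i + 1L] - p$y[i])^2
        n_linked <- n_linked + 1L
      }
    }
  }
  ## every detection that is not the target of a link costs b (either a
  ## birth or a death/non-extension), mirroring the enumeration's terms
  cost + b * (n_det - n_linked - length(trk)) + b * length(trk)
}

test_that("linking matches exhaustive enumeration on small instances", {
  P <- tracking_params(min_track_frames = 2)
  set.seed(5)
  for (r in 1:8) {
    n <- sample(2:4, 1)
    Tn <- sample(4:6, 1)
    starts <- cbind(runif(n, 20, 80), runif(n, 20, 80))
    th <- runif(n, 0, 2 * pi)
    dets <- lapply(seq_len(Tn), function(t) {
      data.frame(x = starts[, 1] + cos(th) * 7 * (t - 1) +
                   rnorm(n, 0, 0.3),
                 y = starts[, 2] + sin(th) * 7 * (t - 1) +
                   rnorm(n, 0, 0.3))
    })
    trk <- link_tracks(dets, P)
    expect_equal(linker_cost(dets, trk, P),
                 exhaustive_link_cost(dets, P), tolerance = 1e-6)
  }
})

test_that("parameter monotonicity holds for gaps and track length", {
  fr <- c(1:4, 10:13)
  dets <- det_frames(fr, 10 + 6 * (fr - 1))
  n_short <- length(link_tracks(dets, tracking_params(max_gap_frames = 2)))
  n_long <- length(link_tracks(dets, tracking_params(max_gap_frames = 8)))
  expect_gte(n_short, n_long)     # larger gap bound merges tracks
  expect_equal(n_long, 1L)

  dets2 <- det_frames(c(1, 2, 4, 5), c(10, 16, 70, 76), Tn = 5)
  n3 <- length(link_tracks(dets2, tracking_params(min_track_frames = 3)))
  n2 <- length(link_tracks(dets2, tracking_params(min_track_frames = 2)))
  expect_gte(n2, n3)
  expect_equal(n2, 2L)
})

test_that("the track partition is invariant under a 90-degree rotation", {
  set.seed(11)
  n <- 5; Tn <- 8
  starts <- cbind(runif(n, 30, 70), runif(n, 30, 70))
  th <- runif(n, 0, 2 * pi)
  dets <- lapply(seq_len(Tn), function(t)
    data.frame(x = starts[, 1] + cos(th) * 6.5 * (t - 1),
               y = starts[, 2] + sin(th) * 6.5 * (t - 1)))
  rot <- lapply(dets, function(d) data.frame(x = -d$y + 120, y = d$x))
  P <- tracking_params()
  sig <- function(trks) {
    s <- lapply(trks, function(tr) tr$points$frame)
    s[order(vapply(s, function(f) f[1] * 1000 + length(f), 0))]
  }
  expect_equal(sig(link_tracks(dets, P)), sig(link_tracks(rot, P)))
})

test_that("particle detection is deterministic and hits noiseless tips", {
  blank <- image2d(matrix(50, 60, 60), 0.1)
  expect_equal(nrow(detect_particles(blank)), 0)

  cfg <- sim_config(rng_seed = 7, frame_interval_s = 2, n_frames = 5,
                    image_shape = c(200, 200), axon_length_um = 10,
                    gaussian_noise_sd = 0)
  sim <- simulate_tracking_movie(cfg, n_tracks = 5, seed = 7)
  fr <- image2d(sim$movie$frames[3, , ], 0.1)
  d1 <- detect_particles(fr, 0.15, min_sep_px = 12)
  d2 <- detect_particles(fr, 0.15, min_sep_px = 12)
  expect_identical(d1, d2)
  tp <- do.call(rbind, lapply(sim$truth, function(df) {
    r <- match(3, df$frame)
    if (is.na(r)) NULL else df[r, c("x", "y")]
  }))
  expect_equal(nrow(d1), nrow(tp))
  err <- vapply(seq_len(nrow(tp)), function(i)
    min(sqrt((d1$x - tp$x[i])^2 + (d1$y - tp$y[i])^2)), 0)
  expect_lt(max(err), 1)
})

test_that("track summaries convert pixels and frames to physical units", {
  P <- tracking_params()          # 2 s interval
  trk <- list(structure(list(points = data.frame(
    frame = 1:5, x = seq(10, 14), y = rep(0, 5)), gap_frames = 0),
    class = "plusend_track"))
  s <- track_summary(trk, 0.1, P)
  expect_equal(s$median_velocity_um_s, 0.05)
  expect_equal(s$median_lifetime_s, 8)
  s0 <- track_summary(list(), 0.1, P)
  expect_equal(s0$n_tracks, 0)
})

test_that("noisy 2D movies are recovered with high recall", {
  P <- tracking_params()
  cfg <- snr5_cfg(31, frame_interval_s = 2, n_frames = 30,
                  image_shape = c(200, 200), axon_length_um = 10,
                  comet_lifetime_mean_s = 30)
  sim <- simulate_tracking_movie(cfg, n_tracks = 10, seed = 31)
  dets <- lapply(seq_len(30), function(t)
    detect_particles(image2d(sim$movie$frames[t, , ], 0.1), 0.15,
                     min_sep_px = 12))
  trk <- link_tracks(dets, P)
  expect_true(isTRUE(validate_tracks(trk, P)))
  m <- match_tracks_2d(sim$truth, trk)
  expect_gte(mean(!is.na(m$track_id)), 0.8)
  ts <- track_summary(trk, 0.1, P)
  mm <- m[!is.na(m$track_id), ]
  verr <- abs(ts$per_track$velocity_um_s[mm$track_id] -
              mm$speed_true_um_s) / mm$speed_true_um_s
  expect_lte(median(verr), 0.1)
})
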