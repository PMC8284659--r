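# Hand-built kymograph with Gaussian ridges at known positions
ridge_kymo <- function(pos_um_by_frame, step_um = 0.1, n_pos = 300,
                       amp = 100, sd_um = 0.3, dt = 1) {
  s <- (seq_len(n_pos) - 1) * step_um
  Tn <- length(pos_um_by_frame[[1]])
  v <- matrix(0, n_pos, Tn)
  for (ridge in pos_um_by_frame) for (t in seq_len(Tn)) {
    if (is.na(ridge[t])) next
    v[, t] <- v[, t] + amp * exp(-(s - ridge[t])^2 / (2 * sd_um^2))
  }
  structure(list(values = v, arclength_step_um = step_um,
                 frame_interval_s = dt), class = "kymograph")
}

test_that("a constant movie yields an exactly constant kymograph", {
  frames <- array(4.2, c(5, 30, 120))
  mv <- movie_stack(frames, 0.1, 1)
  tr <- axon_trace(rbind(c(10, 15), c(110, 15)), 0.1)
  ky <- build_kymograph(mv, tr)
  expect_true(all(ky$values == 4.2))
  expect_equal(ncol(ky$values), 5)
})

test_that("kymograph construction fails when the band leaves the image", {
  frames <- array(1, c(3, 20, 60))
  mv <- movie_stack(frames, 0.1, 1)
  tr <- axon_trace(rbind(c(5, 0.4), c(55, 0.4)), 0.1)   # band exits top
  expect_error(build_kymograph(mv, tr), "arclength")
})

test_that("ridge slopes recover velocity on rendered movies", {
  cfg <- quiet_cfg(comet_velocity_um_s = 0.2, axon_length_um = 30,
                   image_shape = c(48, 340), n_frames = 40)
  tr <- straight_trace(cfg)
  com <- data.frame(birth_time_s = 0, birth_arclength_um = 5,
                    death_time_s = 1e9, velocity_um_s = 0.2,
                    amplitude = 100, tail_length_um = 1)
  mv <- render_movie(tr, com, cfg, noise = FALSE)
  ky <- build_kymograph(mv, tr)
  ## argmax-regression oracle on the raw kymograph columns
  am <- apply(ky$values, 2, which.max)
  s <- (am - 1) * ky$arclength_step_um
  tt <- (seq_len(ncol(ky$values)) - 1) * ky$frame_interval_s
  slope <- unname(coef(lm(s ~ tt))[2])
  expect_equal(slope, 0.2, tolerance = 0.05)

  ## the track extractor agrees and a static comet stays put
  trk <- extract_tracks(ky)
  expect_length(trk, 1)
  expect_equal(trk[[1]]$velocity_um_s, 0.2, tolerance = 0.05)

  com0 <- com; com0$velocity_um_s <- 0
  ky0 <- build_kymograph(render_movie(tr, com0, cfg, noise = FALSE), tr)
  trk0 <- extract_tracks(ky0)
  expect_length(trk0, 1)
  expect_lt(abs(trk0[[1]]$velocity_um_s), 0.02)
})

test_that("track extraction follows the slope and lifetime definitions", {
  expect_length(extract_tracks(ridge_kymo(list(rep(NA_real_, 5)))), 0)

  ## one ridge moving 1.0 um over 5 frames at 1 s
  ridge <- seq(10, 11, length.out = 5)
  trk <- extract_tracks(ridge_kymo(list(ridge)))
  expect_length(trk, 1)
  expect_equal(trk[[1]]$velocity_um_s, 0.25, tolerance = 0.02)
  expect_equal(trk[[1]]$lifetime_s, 4)

  ## gaps within the bound are bridged and count toward lifetime
  gappy <- ridge_kymo(list(c(10, 10.2, NA, NA, 10.8, 11, 11.2)))
  trkg <- extract_tracks(gappy, max_gap_frames = 2)
  expect_length(trkg, 1)
  expect_equal(trkg[[1]]$lifetime_s, 6)
  ## beyond the bound the track splits; the 2-frame tail is discarded
  split <- ridge_kymo(list(c(10, 10.2, 10.4, NA, NA, NA, 11.2, 11.4)))
  trks <- extract_tracks(split, max_gap_frames = 2)
  expect_length(trks, 1)
  expect_equal(nrow(trks[[1]]$points), 3)
})

test_that("reversing the trace negates velocities and keeps lifetimes", {
  cfg <- quiet_cfg(comet_velocity_um_s = 0.2, axon_length_um = 30,
                   image_shape = c(48, 340), n_frames = 30)
  tr <- straight_trace(cfg)
  com <- data.frame(birth_time_s = 0, birth_arclength_um = 8,
                    death_time_s = 25, velocity_um_s = 0.2,
                    amplitude = 100, tail_length_um = 1)
  mv <- render_movie(tr, com, cfg, noise = FALSE)
  rev_tr <- axon_trace(tr$vertices[rev(seq_len(nrow(tr$vertices))), ],
                       tr$pixel_size_um)
  fwd <- extract_tracks(build_kymograph(mv, tr))
  bwd <- extract_tracks(build_kymograph(mv, rev_tr))
  expect_length(fwd, 1); expect_length(bwd, 1)
  expect_equal(bwd[[1]]$velocity_um_s, -fwd[[1]]$velocity_um_s,
               tolerance = 0.01)
  expect_equal(bwd[[1]]$lifetime_s, fwd[[1]]$lifetime_s)
})

test_that("dynamics summaries take medians and flag empties", {
  mk <- function(v) structure(list(points = data.frame(frame = 1:3,
    arclength_um = 1:3), velocity_um_s = v, lifetime_s = 2),
    class = "kymo_track")
  s <- comet_dynamics_summary(lapply(c(0.1, 0.2, 0.3), mk))
  expect_equal(s$median_velocity_um_s, 0.2)
  expect_equal(s$n_tracks, 3)
  s1 <- comet_dynamics_summary(list(mk(0.17)))
  expect_equal(s1$median_velocity_um_s, 0.17)
  s0 <- comet_dynamics_summary(list())
  expect_true(s0$degenerate)
  expect_equal(s0$n_tracks, 0)
})

test_that("a noisy benchmark cohort is recovered track by track", {
  cfg <- snr5_cfg(21, axon_length_um = 30, image_shape = c(48, 340),
                  comet_velocity_um_s = 0.2)
  tr <- straight_trace(cfg)
  com <- benchmark_comets(cfg, n = 20)
  mv <- render_movie(tr, com, cfg)
  trk <- extract_tracks(build_kymograph(mv, tr))
  m <- match_kymo_tracks(com, trk, cfg$frame_interval_s, cfg$n_frames)
  expect_gte(mean(!is.na(m$track_id)), 0.9)
  verr <- abs(m$v_est - m$v_true) / m$v_true
  expect_lte(median(verr, na.rm = TRUE), 0.1)
})
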