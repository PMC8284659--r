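# Shared fixtures: everything is generated in code at test time.

quiet_cfg <- function(...) {
  sim_config(rng_seed = 42, ...)
}

# Straight horizontal trace inside the default image
straight_trace <- function(cfg = quiet_cfg()) {
  simulate_axon_trace(cfg)$trace
}

# Ground-truth rows for static comets at given arclength positions
static_comets <- function(pos_um, amplitude = 100, tail_um = 1) {
  k <- length(pos_um)
  data.frame(birth_time_s = rep(0, k), birth_arclength_um = pos_um,
             death_time_s = rep(1e9, k), velocity_um_s = rep(0, k),
             amplitude = rep_len(amplitude, k),
             tail_length_um = rep_len(tail_um, k))
}

# Config + amplitude calibrated to a peak SNR of 5 over Gaussian noise
snr5_cfg <- function(seed, ...) {
  cfg <- sim_config(rng_seed = seed, gaussian_noise_sd = 3, ...)
  cfg$comet_amplitude <- amplitude_for_snr(cfg, 5)
  do.call(sim_config, unclass(cfg))
}

# Rectangular intensity profile: `n_hi` samples at `hi` above background
rect_profile <- function(n_hi = 20, hi = 100, bg = 0, step = 0.1,
                         pad = 30) {
  v <- c(rep(bg, pad), rep(bg + hi, n_hi), rep(bg, pad))
  intensity_profile(seq_along(v) * step, v, background = bg)
}

with_seed_local <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Analytic rendered comet profile: intrinsic profile convolved with the
# PSF on a dense grid (independent numerical oracle for comet lengths)
analytic_comet_profile <- function(amplitude, tail_um, psf_um, front_um = 0.1,
                                   h = 0.002) {
  d <- seq(-8 * tail_um, 3, by = h)
  intrinsic <- ifelse(d > 0, exp(-d^2 / (2 * front_um^2)), exp(d / tail_um))
  kern <- exp(-seq(-4 * psf_um, 4 * psf_um, by = h)^2 / (2 * psf_um^2))
  kern <- kern / sum(kern)
  nb <- length(kern)
  sm <- stats::filter(c(rep(0, nb), intrinsic, rep(0, nb)), kern, sides = 2)
  list(d = d, profile = amplitude * as.numeric(sm[(nb + 1):(nb + length(d))]))
}

# Brute-force threshold-crossing length of the analytic profile at the
# fractional-peak criterion f
analytic_comet_length <- function(tail_um, psf_um, f = 0.2) {
  ap <- analytic_comet_profile(1, tail_um, psf_um)
  thr <- f * max(ap$profile)
  sum(ap$profile > thr) * (ap$d[2] - ap$d[1])
}
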