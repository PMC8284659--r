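## End-to-end synthetic cohort: conditions with anti-monotone comet
## amount vs curl area, run through rendering, comet measurement, MDI,
## control normalisation and correlation.

#' Simulate a multi-condition cohort with anti-monotone amount vs curling
#'
#' Builds `n_genotypes` conditions whose true comet amplitude decreases
#' while the true curled-bundle area increases, renders stills for each
#' neuron, measures comet amounts from the images, computes the MDI from
#' the ground-truth curl polygons (standing in for freehand
#' annotations), and returns a condition table with metrics
#' `comet_amount` and `mdi` across two biological repeats (each repeat
#' carries its own parallel control, genotype `"control"`).
#'
#' @param n_genotypes number of conditions (the first is the control).
#' @param n_neurons_per_repeat neurons per genotype per repeat.
#' @param seed RNG seed for the whole cohort.
#' @param base_config a [sim_config()]; geometry, PSF, noise and timing
#'   are taken from it.
#' @param amplitude_range true comet amplitude from first to last
#'   genotype (decreasing).
#' @param curl_area_range true total curl area in um^2 from first to last
#'   genotype (increasing).
#' @return List with `table` (condition table), `truth` (data.frame of
#'   per-genotype true amplitude and curl area).
#' @export
sim_amount_mdi_cohort <- function(n_genotypes = 10, n_neurons_per_repeat = 3,
                                  seed = 1,
                                  base_config = sim_config(
                                    axon_length_um = 40,
                                    image_shape = c(80, 480),
                                    gaussian_noise_sd = 2,
                                    rng_seed = NULL),
                                  amplitude_range = c(120, 30),
                                  curl_area_range = c(0.5, 12)) {
  G <- n_genotypes
  f <- (seq_len(G) - 1) / (G - 1)
  amps <- amplitude_range[1] + f * diff(amplitude_range)
  areas <- curl_area_range[1] + f * diff(curl_area_range)
  genos <- c("control", paste0("condition", seq_len(G - 1)))
  rows <- list()
  with_seed(seed, {
    for (g in seq_len(G)) for (rep_i in 1:2) {
      for (nn in seq_len(n_neurons_per_repeat)) {
        cfg <- base_config
        sim <- simulate_axon_trace(cfg, list(c(cfg$axon_length_um / 2,
                                               areas[g])))
        L <- trace_arclength_um(sim$trace)
        k <- 8L
        pos <- sort(runif(k, 2, L - 2))
        while (any(diff(pos) < 2)) pos <- sort(runif(k, 2, L - 2))
        comets <- data.frame(birth_time_s = 0, birth_arclength_um = pos,
                             death_time_s = 1e9, velocity_um_s = 0,
                             amplitude = amps[g] * runif(k, 0.85, 1.15),
                             tail_length_um = cfg$comet_tail_length_um)
        still <- render_still(sim$trace, comets, 0, cfg, noise = TRUE)
        meas <- measure_comets(still, sim$trace,
                               psf_sigma_um = cfg$psf_sigma_um,
                               min_sep_um = 1)
        amount <- if (nrow(meas)) median(meas$amount) else 0
        m <- mdi(lapply(sim$curls, function(cu)
          polygon_roi(cu$polygon_px, "curl")), sim$trace)
        nid <- sprintf("g%02d_r%d_n%02d", g, rep_i, nn)
        rows[[length(rows) + 1L]] <- data.frame(
          neuron_id = paste0(nid, "_amount"), genotype = genos[g],
          biological_repeat = rep_i, metric = "comet_amount",
          value = amount)
        rows[[length(rows) + 1L]] <- data.frame(
          neuron_id = paste0(nid, "_mdi"), genotype = genos[g],
          biological_repeat = rep_i, metric = "mdi", value = m$mdi)
      }
    }
  })
  table <- do.call(rbind, rows)
  table$neuron_id <- sub("_(amount|mdi)$", "", table$neuron_id)
  list(table = table,
       truth = data.frame(genotype = genos, amplitude = amps,
                          curl_area_um2 = areas))
}

#' Correlate normalised comet amount against MDI across conditions
#'
#' Normalises both metrics to parallel controls, summarises each
#' genotype by its centre ([default_center()]: median amount, mean MDI)
#' and returns the Spearman correlation across genotypes.
#'
#' @param table condition table with metrics `comet_amount` and `mdi`.
#' @param control control genotype name.
#' @return List with `per_genotype` (data.frame genotype, amount, mdi)
#'   and `spearman` (result of [spearman_cor()]).
#' @export
correlate_amount_mdi <- function(table, control = "control") {
  ta <- normalise_to_control(table, "comet_amount", control)
  tm <- normalise_to_control(table, "mdi", control)
  genos <- unique(table$genotype)
  amount <- vapply(genos, function(g)
    median(ta$value[ta$metric == "comet_amount" & ta$genotype == g]), 0)
  mdi_v <- vapply(genos, function(g)
    mean(tm$value[tm$metric == "mdi" & tm$genotype == g]), 0)
  list(per_genotype = data.frame(genotype = genos, amount = amount,
                                 mdi = mdi_v),
       spearman = spearman_cor(amount, mdi_v))
}
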