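# Experimental-condition descriptors for the synthetic generator. The preset
# calibrations encode the measured rate distributions, class mixtures and
# initiation-force behaviour of the benchmark conditions.

#' Simulation condition
#'
#' Describes one experimental condition for the synthetic generator: fork
#' velocity distributions (Gaussian, truncated at 0), the probability that an
#' event is bidirectional, the cumulative initiation-force curve sampled for
#' the force-step protocol, expected events per molecule, and post-switch
#' behaviour (continuation probability, rewind rate).
#'
#' Bidirectional events draw independent left/right fork velocities from
#' N(`velocity_bi_mean`/2, `velocity_bi_sd`/sqrt(2)) so that the event-level
#' total expansion rate is N(`velocity_bi_mean`, `velocity_bi_sd`) — the
#' total dark-region expansion is what a single growing dark region measures.
#'
#' @param velocity_uni_mean,velocity_uni_sd unidirectional fork rate, bp/s.
#' @param velocity_bi_mean,velocity_bi_sd total bidirectional expansion rate,
#'   bp/s (sum of the two forks).
#' @param p_bidirectional probability an event is bidirectional.
#' @param initiation_force named numeric vector: cumulative probability that
#'   an event initiates at or below each force (names are forces in pN,
#'   nondecreasing values); remaining mass never initiates (the "N.U.",
#'   no-unwinding, outcome).
#' @param events_per_molecule_mean Poisson mean of nick-initiated events per
#'   molecule when the template does not fix its nicks.
#' @param rewind_rate_bps per-fork reannealing rate after protein removal.
#' @param p_continue per-fork probability of continuing after a channel
#'   switch (1 = switch has no effect).
#' @param spot_channel simulate an eGFP-RPA channel with coil-bound spots.
#' @param label condition label used in summaries.
#' @return an object of class `sim_condition`.
#' @export
sim_condition <- function(velocity_uni_mean, velocity_uni_sd,
                          velocity_bi_mean = velocity_uni_mean,
                          velocity_bi_sd = velocity_uni_sd,
                          p_bidirectional = 0,
                          initiation_force = c("30" = 1),
                          events_per_molecule_mean = 1,
                          rewind_rate_bps = 0, p_continue = 1,
                          spot_channel = FALSE, label = "custom") {
  if (velocity_uni_sd < 0 || velocity_bi_sd < 0) abort("velocity sd must be >= 0")
  if (p_bidirectional < 0 || p_bidirectional > 1) {
    abort("p_bidirectional must lie in [0, 1]")
  }
  if (p_continue < 0 || p_continue > 1) abort("p_continue must lie in [0, 1]")
  q <- initiation_force
  if (is.null(names(q)) || anyNA(suppressWarnings(as.numeric(names(q))))) {
    abort("initiation_force must be named by force in pN")
  }
  if (is.unsorted(as.numeric(names(q))) || is.unsorted(q) ||
      any(q < 0 | q > 1)) {
    abort("initiation_force must be nondecreasing cumulative probabilities")
  }
  structure(list(
    velocity_uni_mean = velocity_uni_mean, velocity_uni_sd = velocity_uni_sd,
    velocity_bi_mean = velocity_bi_mean, velocity_bi_sd = velocity_bi_sd,
    p_bidirectional = p_bidirectional, initiation_force = q,
    events_per_molecule_mean = events_per_molecule_mean,
    rewind_rate_bps = rewind_rate_bps, p_continue = p_continue,
    spot_channel = spot_channel, label = label),
    class = "sim_condition")
}

#' Calibrated benchmark conditions
#'
#' * `blm_alone_30pN` — full-length helicase without ssDNA-binding protein:
#'   purely unidirectional, 60 +/- 9 bp/s at 30 pN, one-to-few events per
#'   molecule.
#' * `blm_rpa_30pN` — helicase with RPA: 53% bidirectional; unidirectional
#'   72 +/- 24 bp/s, bidirectional total 117 +/- 25 bp/s; 3.4 events per
#'   molecule; eGFP-RPA spot channel on; initiation possible from 5 pN.
#' * `corebm_rpa_35pN` — core helicase fragment with RPA at 35 pN: 42%
#'   bidirectional, slower rates with a 1.7-fold bidirectional/unidirectional
#'   ratio.
#' * `nicked_6p4` — single-nick 6.4 kbp polarity assay condition at 30 pN,
#'   unidirectional 60 +/- 9 bp/s.
#'
#' @param name preset name.
#' @return a [sim_condition()].
#' @export
sim_condition_preset <- function(name = c("blm_alone_30pN", "blm_rpa_30pN",
                                          "corebm_rpa_35pN", "nicked_6p4")) {
  name <- match.arg(name)
  init_blm <- c("10" = 0.30, "20" = 0.60, "30" = 0.90, "40" = 0.95)
  init_rpa <- c("5" = 0.50, "10" = 0.70, "20" = 0.85, "30" = 0.95, "40" = 1.00)
  switch(name,
    blm_alone_30pN = sim_condition(
      velocity_uni_mean = 60, velocity_uni_sd = 9, p_bidirectional = 0,
      initiation_force = init_blm, events_per_molecule_mean = 1.6,
      label = "blm_alone_30pN"),
    blm_rpa_30pN = sim_condition(
      velocity_uni_mean = 72, velocity_uni_sd = 24,
      velocity_bi_mean = 117, velocity_bi_sd = 25, p_bidirectional = 0.53,
      initiation_force = init_rpa, events_per_molecule_mean = 3.4,
      spot_channel = TRUE, label = "blm_rpa_30pN"),
    corebm_rpa_35pN = sim_condition(
      velocity_uni_mean = 42, velocity_uni_sd = 14,
      velocity_bi_mean = 71.4, velocity_bi_sd = 18, p_bidirectional = 0.42,
      initiation_force = init_rpa, events_per_molecule_mean = 3.4,
      spot_channel = TRUE, label = "corebm_rpa_35pN"),
    nicked_6p4 = sim_condition(
      velocity_uni_mean = 60, velocity_uni_sd = 9, p_bidirectional = 0,
      initiation_force = init_blm, events_per_molecule_mean = 1,
      label = "nicked_6p4"))
}

#' Imaging and raster parameters for the synthetic generator
#'
#' Typical confocal line-scan values; all overridable.
#'
#' @param pixel_size_um pixel size along the scan, micrometres.
#' @param line_time_s time per scan line, seconds.
#' @param psf_sigma_um Gaussian point-spread-function sigma, micrometres
#'   (a warning is issued below `pixel_size_um / 2`).
#' @param dsdna_counts expected photon counts per fully duplex-covered pixel.
#' @param background_counts expected background counts per pixel.
#' @param spot_counts_per_knt expected total eGFP counts per 1,000 coil nt.
#' @param duration_s trace duration, seconds.
#' @param noise apply Poisson photon noise and length-readout noise; turn
#'   off for noiseless oracle traces.
#' @param length_noise_um Gaussian sd of the length readout, micrometres.
#' @param bead_margin_px bright bead-glow pixels padded at both raster ends.
#' @return an object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size_um = 0.1, line_time_s = 0.1,
                           psf_sigma_um = 0.15, dsdna_counts = 50,
                           background_counts = 5, spot_counts_per_knt = 200,
                           duration_s = 60, noise = TRUE,
                           length_noise_um = 0.005, bead_margin_px = 5L) {
  vals <- c(pixel_size_um, line_time_s, psf_sigma_um, dsdna_counts,
            background_counts, spot_counts_per_knt, duration_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all imaging parameters must be positive")
  }
  if (psf_sigma_um < pixel_size_um / 2) {
    warn("psf_sigma_um below pixel_size_um/2: raster undersamples the PSF")
  }
  structure(list(pixel_size_um = pixel_size_um, line_time_s = line_time_s,
                 psf_sigma_um = psf_sigma_um, dsdna_counts = dsdna_counts,
                 background_counts = background_counts,
                 spot_counts_per_knt = spot_counts_per_knt,
                 duration_s = duration_s, noise = noise,
                 length_noise_um = length_noise_um,
                 bead_margin_px = as.integer(bead_margin_px)),
            class = "imaging_params")
}

#' Force-step schedule
#'
#' A sequence of constant-force plateaus, as in the stepped protocol that
#' raises the force until unwinding is detected.
#'
#' @param force_pN plateau forces, pN.
#' @param duration_s plateau durations, seconds (recycled).
#' @return a tibble with `force_pN`, `t_start_s`, `t_end_s`.
#' @export
#' @examples
#' force_schedule(c(10, 20, 30, 40), 60)   # the stepped protocol
#' force_schedule(30, 60)                  # a single constant-force plateau
force_schedule <- function(force_pN, duration_s) {
  stopifnot(length(force_pN) >= 1, all(force_pN > 0), all(duration_s > 0))
  duration_s <- rep_len(duration_s, length(force_pN))
  ends <- cumsum(duration_s)
  tibble(force_pN = as.numeric(force_pN),
         t_start_s = c(0, ends[-length(ends)]), t_end_s = ends)
}

# plateau force at given times (vectorised); times beyond the schedule get
# the last plateau's force
schedule_force_at <- function(schedule, time_s) {
  idx <- findInterval(time_s, schedule$t_start_s)
  idx[idx < 1] <- 1
  schedule$force_pN[pmin(idx, nrow(schedule))]
}
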