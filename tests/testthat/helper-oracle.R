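# Independent per-molecule Monte Carlo oracle for deuterium release:
# each of n_molecules activated methane molecules is CH3D with probability
# f_ch3d; an activated CH3D releases its single deuterium with probability
# n_exchange / 4. Returns the realised mean D release per activated molecule.
mc_d_release <- function(n_molecules, f_ch3d, n_exchange, seed) {
  withr::with_seed(seed, {
    n_chd <- rbinom(1, n_molecules, f_ch3d)
    released <- rbinom(1, n_chd, n_exchange / 4)
    released / n_molecules
  })
}

# A clean 4-rounds-of-10 injection table for one analyte.
make_rounds <- function(sample_id, delta, n_rounds = 4, per_round = 10,
                        start_pos = 0) {
  tibble::tibble(
    sample_id = sample_id,
    round = rep(seq_len(n_rounds), each = per_round),
    injection = rep(seq_len(per_round), n_rounds),
    raw_delta_d = delta,
    temp_change_rate = 0,
    pressure_rising = FALSE,
    position = start_pos + seq_len(n_rounds * per_round)
  )
}

two_standards <- function() {
  tibble::tibble(standard_id = c("std_hi", "std_lo"),
                 known_delta_d = c(0.5, -73.4))
}

# Minimal run: one calibration segment's worth of standards plus samples.
# Standards are given one round of `per_round` injections each at the head
# of every `segment_size` span.
make_run <- function(sample_deltas, std_measured = c(0.5, -73.4),
                     per_round = 10) {
  std <- two_standards()
  blocks <- list(
    make_rounds(std$standard_id[1], std_measured[1], n_rounds = 1,
                per_round = per_round, start_pos = 0),
    make_rounds(std$standard_id[2], std_measured[2], n_rounds = 1,
                per_round = per_round, start_pos = per_round)
  )
  pos <- 2 * per_round
  for (nm in names(sample_deltas)) {
    blocks <- c(blocks, list(
      make_rounds(nm, sample_deltas[[nm]], n_rounds = 2,
                  per_round = per_round, start_pos = pos)))
    pos <- pos + 2 * per_round
  }
  analysis_run(dplyr::bind_rows(blocks), std)
}

# Culture-geometry recovery experiment used by the recovery tests: true
# rate drawn log-uniform in [10, 1000] nmol cm-3 d-1, pure-CH3D headspace,
# n_exchange_true 2 analysed with the matched stoichiometric factor.
recovery_error <- function(seed) {
  rate <- withr::with_seed(seed, 10^runif(1, 1, 3))
  inc <- incubation_spec("cult", water_volume_l = 0.00944,
                         inoculum_volume_cm3 = 9.44, f_ch3d = 1,
                         headspace_pa = c(ch3d = 1e5))
  cfg <- simulation_config(rate_nmol_cm3_d = rate, n_exchange_true = 2,
                           incubation = inc,
                           sampling_times_h = seq(0, 480, by = 80),
                           seed = seed)
  res <- analyze_experiment(simulate_experiment(cfg),
                            stoichiometric_factor = 2)
  abs(res$endpoint$rate_nmol_cm3_d - rate) / rate
}

noise_free_config <- function(...) {
  simulation_config(injection_sd_permil = 0, memory_coeff = 0,
                    drift_per_injection_permil = 0, counting_cv = 0, ...)
}
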