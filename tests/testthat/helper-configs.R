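# Reduced experiment for fast tests: the scan window covers only the two
# regions of interest plus margins, with a thinned delay schedule.
small_experiment <- function(seed = 1, shots_per_setting = 250) {
  experiment_config(
    photon_energies = seq(524.5, 534, 0.5),
    delay_schedule = c(seq(-200, 400, 50), seq(600, 3000, 400),
                       seq(4000, 12000, 2000), 16000, 20000),
    shots_per_setting = shots_per_setting,
    seed = seed)
}

small_binning <- function(...) binning_spec(n_intensity_bins = 2, ...)

# Noise-free shot table bypassing the stochastic generator: exact yields,
# unit intensity, deterministic UV interleaving, zero jitter. `n_per` must
# be even so UV-on and UV-off halves are balanced.
noisefree_shots <- function(energies, delays, n_per = 4,
                            params = kinetic_params(),
                            spectra = default_spectra(grid = energies),
                            delta = 0) {
  stopifnot(n_per %% 2 == 0)
  g <- expand.grid(photon_energy = energies, nominal_delay = delays,
                   rep = seq_len(n_per))
  uv <- g$rep %% 2 == 0
  yield <- true_absorption(g$photon_energy, g$nominal_delay + delta, uv,
                           params, spectra)
  dt <- data.table::data.table(
    shot_id = seq_len(nrow(g)),
    photon_energy = g$photon_energy,
    nominal_delay = g$nominal_delay,
    measured_jitter = delta,
    xray_intensity = 1,
    uv_on = uv,
    auger_yield = yield)
  data.table::setattr(dt, "class",
                      c("shot_table", class(data.table::data.table())))
  dt[]
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y)), tol)
}
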