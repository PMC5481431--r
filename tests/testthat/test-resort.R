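test_that("jitter correction is exact arithmetic and drops unmeasured shots", {
  dt <- data.table::data.table(shot_id = 1:3, photon_energy = 526.5,
                               nominal_delay = c(-100, 50, 0),
                               measured_jitter = c(150, 0, NA),
                               xray_intensity = 1, uv_on = TRUE,
                               auger_yield = 1L)
  expect_message(out <- jitter_correct(dt), "dropped")
  expect_equal(nrow(out), 2)
  expect_equal(out$corrected_delay, c(50, 50))
  expect_equal(attr(out, "dropped_shots"), 1)

  # with the synthesizer the correction recovers the true delay exactly
  shots <- jitter_correct(generate_shots(small_experiment(seed = 4,
                                                          shots_per_setting = 2)))
  expect_equal(stats::var(shots$corrected_delay -
                            (shots$nominal_delay + shots$measured_jitter)), 0)
})

test_that("with zero jitter and one intensity bin the difference map equals
           the naive group-by oracle", {
  energies <- seq(525, 533, 1)
  delays <- c(-100, 0, 100, 2000)  # one 50 fs bin per setting
  cfg <- experiment_config(photon_energies = energies,
                           delay_schedule = delays,
                           shots_per_setting = 40, jitter_sigma_fs = 0,
                           seed = 9)
  shots <- jitter_correct(generate_shots(cfg))
  map <- bin_and_difference(shots, binning_spec(n_intensity_bins = 1))

  oracle <- shots[, .(m = mean(auger_yield / xray_intensity)),
                  by = .(nominal_delay, photon_energy, uv_on)]
  oracle <- data.table::dcast(oracle, nominal_delay + photon_energy ~ uv_on,
                              value.var = "m")
  oracle[, d := `TRUE` - `FALSE`]
  data.table::setorder(oracle, nominal_delay, photon_energy)
  expect_equal(map$diff, oracle$d, tolerance = 1e-12)
  expect_equal(map$delay_mean_fs,
               sort(unique(shots$corrected_delay))[
                 match(map$delay_fs, sort(unique(map$delay_fs)))],
               tolerance = 1e-12)
})

test_that("noise-free shots reproduce the model difference spectrum exactly", {
  energies <- seq(524.5, 534, 0.5)
  sp <- default_spectra(grid = energies)
  p <- kinetic_params()
  shots <- jitter_correct(noisefree_shots(energies, c(-175, 25, 2025),
                                          n_per = 12, params = p,
                                          spectra = sp))
  map <- bin_and_difference(shots, binning_spec(n_intensity_bins = 1,
                                                min_shots_per_cell = 2))
  pop <- model_populations(p, 2025)
  model_diff <- (1 - pop$gs_deficit) * sp$GS$intensity +
    pop$pipi * sp$pipi$intensity +
    (pop$npi1 + pop$npi2) * sp$npi$intensity - sp$GS$intensity
  got <- map[delay_fs == 2025]
  expect_equal(got$diff, model_diff, tolerance = 1e-10)
})

test_that("difference maps are invariant under a common yield/intensity
           scale and refine conservatively", {
  cfg <- small_experiment(seed = 12, shots_per_setting = 60)
  shots <- jitter_correct(generate_shots(cfg))
  map1 <- bin_and_difference(shots, small_binning())
  scaled <- data.table::copy(shots)
  scaled[, `:=`(auger_yield = auger_yield * 7,
                xray_intensity = xray_intensity * 7)]
  map2 <- bin_and_difference(scaled, small_binning())
  expect_equal(map2$diff, map1$diff, tolerance = 1e-12)

  # refinement: noise-free shots at four sub-bin delays; the shot-weighted
  # mean of the 50 fs bins over [0, 100) equals the 100 fs bin value
  energies <- c(526.5, 531.5)
  shots_nf <- jitter_correct(noisefree_shots(energies,
                                             c(12.5, 37.5, 62.5, 87.5),
                                             n_per = 4))
  coarse <- bin_and_difference(shots_nf,
                               binning_spec(100, 1, min_shots_per_cell = 2))
  fine <- bin_and_difference(shots_nf,
                             binning_spec(50, 1, min_shots_per_cell = 2))
  for (en in energies) {
    f <- fine[energy_eV == en]
    expect_equal(sum(f$diff * f$n_shots) / sum(f$n_shots),
                 coarse[energy_eV == en, diff], tolerance = 1e-12)
  }
})

test_that("cells lacking an on/off partner are flagged missing, not zero", {
  dt <- data.table::data.table(
    shot_id = 1:40, photon_energy = rep(c(526.5, 531.5), each = 20),
    nominal_delay = 0, measured_jitter = 0, xray_intensity = 1,
    uv_on = rep(c(TRUE, FALSE), 20), auger_yield = rpois(40, 5))
  dt[photon_energy == 531.5, uv_on := TRUE]  # no UV-off partner there
  map <- bin_and_difference(jitter_correct(dt),
                            binning_spec(n_intensity_bins = 1,
                                         min_shots_per_cell = 2))
  expect_equal(map$energy_eV, 526.5)
  expect_equal(attr(map, "missing_cells"), 1)
})

test_that("ROI integration sums the window with quadrature errors and
           rejects empty windows", {
  cfg <- small_experiment(seed = 13, shots_per_setting = 60)
  map <- bin_and_difference(jitter_correct(generate_shots(cfg)),
                            small_binning())
  expect_error(integrate_roi(map, c(600, 610)), "overlap")

  tr <- integrate_roi(map, c(524, 535))
  row <- map[delay_fs == tr$delay_fs[1]]
  expect_equal(tr$signal[1], sum(row$diff) * attr(map, "energy_step"))
  expect_equal(tr$se[1], sqrt(sum(row$se^2)) * attr(map, "energy_step"))

  # zero map integrates to zero
  zero <- data.table::copy(map)[, `:=`(diff = 0, se = 1)]
  data.table::setattr(zero, "class", class(map))
  data.table::setattr(zero, "energy_step", attr(map, "energy_step"))
  expect_true(all(integrate_roi(zero, c(524, 535))$signal == 0))
})

test_that("ROI traces carry the published sign structure", {
  cfg <- small_experiment(seed = 14)
  map <- bin_and_difference(jitter_correct(generate_shots(cfg)),
                            small_binning())
  exc <- integrate_roi(map, c(525, 528))
  ble <- integrate_roi(map, c(530.5, 533))
  late <- function(tr) tr[delay_fs > 500 & delay_fs < 3000]
  expect_true(all(late(exc)$signal > 0))
  expect_true(all(late(ble)$signal < 0))
  pre <- function(tr) tr[delay_fs < -150]
  expect_lt(max(abs(pre(exc)$signal / pre(exc)$se)), 4)
})

test_that("the best signal-to-noise window wins, deterministically", {
  cfg <- small_experiment(seed = 15)
  map <- bin_and_difference(jitter_correct(generate_shots(cfg)),
                            small_binning())
  single <- select_snr_roi(map, list(c(525, 528)))
  expect_equal(as.numeric(single), c(525, 528))

  best <- select_snr_roi(map, list(c(533.2, 534), c(525, 528)))
  expect_equal(as.numeric(best), c(525, 528))  # noise-only window loses

  tie <- select_snr_roi(map, list(c(525, 528), c(525, 528)))
  expect_equal(as.numeric(tie), c(525, 528))
})
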