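test_that("noise-free traces return the generator parameters to 0.1%", {
  p <- kinetic_params()
  tt <- c(seq(-200, 500, 25), seq(600, 3000, 200), seq(3500, 20000, 500))
  mk <- function(kind, a) {
    tr <- data.table::data.table(
      delay_fs = tt, delay_mean_fs = tt,
      signal = roi_signal(p, tt, kind, amplitude = a),
      se = 1e-4 * a * p$f_exc, n_shots = 1000L)
    data.table::setattr(tr, "class",
                        c("time_trace", class(data.table::data.table())))
    tr[]
  }
  fit <- fit_kinetics(list(excited = mk("excited_526", 38),
                           bleach = mk("bleach_pi", 40)))
  expect_true(fit$convergence)
  for (chk in list(c("t0_fs", 0), c("tau1_fs", 60), c("tau2_ps", 1.9),
                   c("tau3_ps", 10.5), c("a_excited", 38),
                   c("a_bleach", 40))) {
    v <- fit_value(fit, chk[1])[["value"]]
    truth <- as.numeric(chk[2])
    if (truth == 0) expect_lt(abs(v), 0.1)
    else expect_lt(abs(v - truth) / truth, 1e-3)
  }
})

test_that("the fit demands enough points and reports structured output", {
  p <- kinetic_params()
  tiny <- data.table::data.table(delay_fs = c(0, 100, 200),
                                 delay_mean_fs = c(0, 100, 200),
                                 signal = 1:3, se = 1, n_shots = 10L)
  data.table::setattr(tiny, "class",
                      c("time_trace", class(data.table::data.table())))
  expect_error(fit_kinetics(tiny), "3x")

  tt <- seq(-200, 20000, 250)
  tr <- data.table::data.table(delay_fs = tt, delay_mean_fs = tt,
                               signal = roi_signal(p, tt, "excited_526", 38),
                               se = 0.02, n_shots = 100L)
  data.table::setattr(tr, "class",
                      c("time_trace", class(data.table::data.table())))
  fit <- fit_kinetics(tr, free = c("t0_fs", "tau1_fs", "tau2_ps",
                                   "tau3_ps", "a_excited"))
  expect_true(fit$convergence)
  expect_named(fit$coef, c("name", "value", "se", "fixed"))
  expect_true(all(fit$coef$se[!fit$coef$fixed] >= 0))
  expect_true(all(is.na(fit$coef$se[fit$coef$fixed])))
  expect_equal(dim(fit$covariance), c(5, 5))

  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_true(rep$converged)
  expect_equal(rep$parameters$tau1_fs$value, fit_value(fit, "tau1_fs")[[1]],
               tolerance = 1e-9)
})

test_that("parameter recovery is unbiased with calibrated errors over
           seeded replicates", {
  p <- kinetic_params()
  reps <- lapply(1:20, function(s) {
    shots <- generate_shots(small_experiment(seed = 100 + s), p)
    map <- bin_and_difference(jitter_correct(shots), small_binning())
    fit <- fit_kinetics(list(excited = integrate_roi(map, c(525, 528)),
                             bleach = integrate_roi(map, c(530.5, 533))),
                        n_starts = 3)
    expect_true(fit$convergence)
    vals <- sapply(c("tau1_fs", "tau2_ps", "tau3_ps"), function(nm)
      fit_value(fit, nm))
    stats::setNames(as.numeric(vals),
                    c("tau1.value", "tau1.se", "tau2.value", "tau2.se",
                      "tau3.value", "tau3.se"))
  })
  reps <- do.call(rbind, reps)
  truth <- c(tau1 = 60, tau2 = 1.9, tau3 = 10.5)
  for (nm in names(truth)) {
    v <- reps[, paste0(nm, ".value")]
    s <- reps[, paste0(nm, ".se")]
    expect_lt(abs(stats::median(v) - truth[[nm]]), stats::median(s))
  }
  covered <- sapply(names(truth), function(nm) {
    abs(reps[, paste0(nm, ".value")] - truth[[nm]]) <=
      1.96 * reps[, paste0(nm, ".se")]
  })
  expect_gte(mean(covered), 0.80)
  expect_lte(mean(covered), 0.99)
})

test_that("the bleach alone never constrains the onset delay better than
           the joint fit", {
  shots <- generate_shots(small_experiment(seed = 31), kinetic_params())
  map <- bin_and_difference(jitter_correct(shots), small_binning())
  exc <- integrate_roi(map, c(525, 528))
  ble <- integrate_roi(map, c(530.5, 533))
  free_b <- c("t0_fs", "tau1_fs", "a_bleach")
  joint <- fit_kinetics(list(excited = exc, bleach = ble),
                        free = c(free_b, "a_excited"))
  alone <- fit_kinetics(list(bleach = ble), free = free_b)
  expect_true(joint$convergence && alone$convergence)
  expect_gte(fit_value(alone, "tau1_fs")[["se"]],
             fit_value(joint, "tau1_fs")[["se"]])
})

test_that("peak detection refines to sub-grid accuracy and is
           translation-equivariant", {
  g <- energy_grid(520, 535, 0.05)
  single <- nexafs_spectrum(g, stats::dnorm(g, 526.4, 0.3))
  pk <- detect_peaks(single)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position_eV, 526.4, tolerance = 0.005)
  expect_equal(pk$fwhm_eV, 0.3 * 2 * sqrt(2 * log(2)), tolerance = 0.02)

  expect_equal(nrow(detect_peaks(nexafs_spectrum(g, rep(1, length(g))))), 0)

  g2 <- energy_grid(528, 536, 0.01)
  two <- nexafs_spectrum(g2, stats::dnorm(g2, 531.4, 0.2973) +
                           0.9 * stats::dnorm(g2, 532.2, 0.2973))
  pk2 <- detect_peaks(two)
  expect_equal(pk2$position_eV, c(531.4, 532.2), tolerance = 0.05)

  delta <- 1.37
  shifted <- nexafs_spectrum(g2 + delta, two$intensity)
  expect_equal(detect_peaks(shifted)$position_eV,
               pk2$position_eV + delta, tolerance = 1e-9)
})

test_that("excitation-fraction estimation recovers the generator value,
           scales linearly, and vanishes without pump transfer", {
  sp_small <- default_spectra(grid = small_experiment()$photon_energies)

  est <- local({
    shots <- generate_shots(small_experiment(seed = 41))
    map <- bin_and_difference(jitter_correct(shots), small_binning())
    estimate_excitation_fraction(map, sp_small)
  })
  expect_true(est$reliable)
  expect_lt(abs(est$estimate - 0.13), 2 * est$se)

  # noise-free linearity: doubling f_exc doubles the estimate
  energies <- small_experiment()$photon_energies
  est_nf <- function(fe) {
    p <- kinetic_params(f_exc = fe)
    shots <- jitter_correct(noisefree_shots(energies, seq(600, 2800, 200),
                                            n_per = 4, params = p,
                                            spectra = sp_small))
    map <- bin_and_difference(shots, binning_spec(n_intensity_bins = 1,
                                                  min_shots_per_cell = 2))
    estimate_excitation_fraction(map, sp_small)$estimate
  }
  expect_equal(est_nf(0.1), 0.1, tolerance = 1e-3)
  expect_equal(est_nf(0.2) / est_nf(0.1), 2, tolerance = 1e-3)

  # f_exc = 0: consistent with zero and flagged unreliable
  shots0 <- generate_shots(small_experiment(seed = 42),
                           kinetic_params(f_exc = 1e-4))
  map0 <- bin_and_difference(jitter_correct(shots0), small_binning())
  est0 <- estimate_excitation_fraction(map0, sp_small)
  expect_lt(abs(est0$estimate), 4 * est0$se)
  expect_false(est0$reliable)
})
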