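.fit_free_default <- c("t0_fs", "tau1_fs", "tau2_ps", "tau3_ps",
                       "a_excited", "a_bleach")

# Assemble the full parameter vector (kinetic params + trace amplitudes)
.full_par <- function(init, a_excited, a_bleach) {
  c(unlist(unclass(init)), a_excited = a_excited, a_bleach = a_bleach)
}

.par_to_model <- function(theta) {
  kp <- do.call(kinetic_params,
                as.list(theta[setdiff(names(theta),
                                      c("a_excited", "a_bleach"))]))
  list(params = kp, a_excited = unname(theta[["a_excited"]]),
       a_bleach = unname(theta[["a_bleach"]]))
}

.trace_times <- function(tr) {
  if ("delay_mean_fs" %in% names(tr) && all(is.finite(tr$delay_mean_fs)))
    tr$delay_mean_fs else tr$delay_fs
}

# Model value of a binned trace point: the signal averaged over the shots
# in a delay bin is, to second order in the within-bin delay spread,
# m(t_mean) + var/2 * m''(t_mean). Without the curvature term the finite
# bin width acts as extra temporal smearing and biases the onset delay.
.binned_signal <- function(params, tr, roi_kind, amplitude, h = 20) {
  t <- .trace_times(tr)
  m <- roi_signal(params, t, roi_kind, amplitude = amplitude)
  if ("delay_var_fs2" %in% names(tr) && any(tr$delay_var_fs2 > 0)) {
    d2 <- (roi_signal(params, t + h, roi_kind, amplitude = amplitude) -
             2 * m +
             roi_signal(params, t - h, roi_kind, amplitude = amplitude)) /
      h^2
    m <- m + 0.5 * tr$delay_var_fs2 * d2
  }
  m
}

.fit_residuals <- function(theta, traces) {
  md <- tryCatch(.par_to_model(theta), error = function(e) NULL)
  if (is.null(md)) {   # invalid excursion: steer the optimizer back
    n <- sum(vapply(traces, nrow, integer(1)))
    return(rep(1e8, n))
  }
  res <- numeric(0)
  if (!is.null(traces$excited)) {
    tr <- traces$excited
    mod <- .binned_signal(md$params, tr, "excited_526", md$a_excited)
    res <- c(res, (tr$signal - mod) / tr$se)
  }
  if (!is.null(traces$bleach)) {
    tr <- traces$bleach
    mod <- .binned_signal(md$params, tr, "bleach_pi", md$a_bleach)
    res <- c(res, (tr$signal - mod) / tr$se)
  }
  res
}

# Central-difference Jacobian of the weighted residual vector
.fit_jacobian <- function(theta, free, traces) {
  r0 <- .fit_residuals(theta, traces)
  J <- matrix(0, length(r0), length(free))
  for (j in seq_along(free)) {
    h <- max(abs(theta[[free[j]]]) * 1e-6, 1e-8)
    tp <- tm <- theta
    tp[[free[j]]] <- tp[[free[j]]] + h
    tm[[free[j]]] <- tm[[free[j]]] - h
    J[, j] <- (.fit_residuals(tp, traces) - .fit_residuals(tm, traces)) /
      (2 * h)
  }
  J
}

.fit_bounds <- function(names) {
  lower <- c(t0_fs = -Inf, irf_fwhm_fs = 1, tau1_fs = 1, tau2_ps = 1e-3,
             tau3_ps = 1e-3, f_exc = 1e-4, w_pipi = 0, w_npi1 = 0,
             w_npi2 = 0, phi_recovery = 0, a_excited = 0, a_bleach = 0)
  upper <- c(t0_fs = Inf, irf_fwhm_fs = Inf, tau1_fs = Inf, tau2_ps = Inf,
             tau3_ps = Inf, f_exc = 1, w_pipi = Inf, w_npi1 = Inf,
             w_npi2 = Inf, phi_recovery = 1, a_excited = Inf,
             a_bleach = Inf)
  list(lower = lower[names], upper = upper[names])
}

#' Fit the sequential kinetic model to ROI time traces
#'
#' Weighted (1/SE^2) nonlinear least squares of the IRF-convolved sequential
#' rate-equation model, jointly over the supplied excited-state and/or
#' bleach traces, using bounded Levenberg-Marquardt minimization with
#' multi-start initialization (log-uniform perturbations of the positive
#' parameters, fixed sub-seeds) to avoid local minima. Parameter standard
#' errors come from the Jacobian-based covariance scaled by the reduced
#' chi-square.
#'
#' @param traces Either a single `time_trace` (taken as the excited-state
#'   trace) or a named list with elements `excited` and/or `bleach` from
#'   [integrate_roi()].
#' @param init A [kinetic_params()] with starting values; fixed parameters
#'   keep these values.
#' @param free Character vector of free parameter names among the
#'   [kinetic_params()] fields plus the trace amplitudes `a_excited`,
#'   `a_bleach`. The default frees time zero, the three lifetimes and the
#'   amplitudes, keeping the IRF fixed at the known pulse durations.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Seed for the start perturbations.
#' @return Object of class `kinetics_fit`: fitted parameters with standard
#'   errors (`$coef`), the covariance of the free parameters, the reduced
#'   chi-square, and a convergence flag. On non-convergence the result is
#'   flagged and no values are reported as valid.
#' @export
fit_kinetics <- function(traces, init = kinetic_params(),
                         free = .fit_free_default, n_starts = 5,
                         seed = 42) {
  if (inherits(traces, "time_trace")) traces <- list(excited = traces)
  stopifnot(is.list(traces),
            all(names(traces) %in% c("excited", "bleach")),
            length(traces) >= 1, inherits(init, "kinetic_params"))
  # points without a usable error bar (e.g. zero-count cells) carry no
  # defined weight and are excluded
  traces <- lapply(traces, function(tr) tr[is.finite(tr$se) & tr$se > 0])
  n_obs <- sum(vapply(traces, nrow, integer(1)))
  if (n_obs < 3 * length(free))
    stop("need at least 3x as many trace points as free parameters")

  # amplitude auto-initialization from the data scale
  a_exc0 <- a_ble0 <- 1
  if (!is.null(traces$excited)) {
    m <- roi_signal(init, .trace_times(traces$excited), "excited_526")
    if (max(abs(m)) > 0)
      a_exc0 <- max(abs(traces$excited$signal)) / max(abs(m))
  }
  if (!is.null(traces$bleach)) {
    m <- roi_signal(init, .trace_times(traces$bleach), "bleach_pi")
    if (max(abs(m)) > 0)
      a_ble0 <- max(abs(traces$bleach$signal)) / max(abs(m))
  }
  theta0 <- .full_par(init, a_exc0, a_ble0)
  stopifnot(all(free %in% names(theta0)))
  bounds <- .fit_bounds(free)

  set.seed(seed)
  starts <- list(theta0[free])
  if (n_starts > 1) for (i in seq_len(n_starts - 1)) {
    s <- theta0[free]
    for (nm in free) {
      if (nm == "t0_fs") s[nm] <- s[nm] + stats::runif(1, -50, 50)
      else s[nm] <- s[nm] * exp(stats::runif(1, -log(1.5), log(1.5)))
    }
    starts[[i + 1]] <- pmin(pmax(s, bounds$lower), bounds$upper)
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s,
        lower = bounds$lower, upper = bounds$upper,
        fn = function(p) {
          th <- theta0
          th[free] <- p
          .fit_residuals(th, traces)
        },
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  converged <- !is.null(best)
  coef_tab <- data.frame(name = names(theta0),
                         value = unname(theta0),
                         se = NA_real_,
                         fixed = !(names(theta0) %in% free))
  covariance <- NULL
  chi2_red <- NA_real_
  if (converged) {
    theta <- theta0
    theta[free] <- best$par
    coef_tab$value <- unname(theta)
    chi2_red <- best$deviance / (n_obs - length(free))
    J <- .fit_jacobian(theta, free, traces)
    covariance <- tryCatch(chi2_red * solve(crossprod(J)),
                           error = function(e) NULL)
    if (!is.null(covariance)) {
      dimnames(covariance) <- list(free, free)
      coef_tab$se[match(free, coef_tab$name)] <- sqrt(diag(covariance))
    } else converged <- FALSE
  }
  structure(list(coef = coef_tab,
                 params = if (converged)
                   .par_to_model(stats::setNames(coef_tab$value,
                                                 coef_tab$name))$params
                   else NULL,
                 covariance = covariance,
                 chi2_red = chi2_red,
                 convergence = converged,
                 n_obs = n_obs, free = free),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %s, chi2_red = %.3g, n = %d\n",
              if (x$convergence) "converged" else "NOT CONVERGED",
              x$chi2_red, x$n_obs))
  tab <- x$coef
  tab$value <- signif(tab$value, 6)
  tab$se <- signif(tab$se, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract a fitted value and its standard error
#'
#' @param fit A `kinetics_fit`.
#' @param name Parameter name.
#' @return Named numeric vector `c(value, se)`.
#' @export
fit_value <- function(fit, name) {
  i <- match(name, fit$coef$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  c(value = fit$coef$value[i], se = fit$coef$se[i])
}

#' Serialize a fit as a JSON report
#'
#' @param fit A `kinetics_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(converged = fit$convergence, chi2_red = fit$chi2_red,
              n_obs = fit$n_obs,
              parameters = stats::setNames(lapply(seq_len(nrow(fit$coef)),
                function(i) list(value = fit$coef$value[i],
                                 se = fit$coef$se[i],
                                 fixed = fit$coef$fixed[i])),
                fit$coef$name))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Detect peaks in a model spectrum
#'
#' Local maxima above a prominence threshold, refined to sub-grid positions
#' by three-point parabolic interpolation. Peak widths are estimated from
#' the local curvature assuming a Gaussian profile.
#'
#' @param spectrum A [nexafs_spectrum()]; the grid step should be at most
#'   a fifth of the peak width for reliable refinement.
#' @param min_prominence Minimum prominence (height above the higher of the
#'   two flanking key saddles); default 1% of the spectrum maximum.
#' @return data.frame with columns `position_eV`, `height`, `fwhm_eV`,
#'   sorted by position; empty if nothing exceeds the prominence.
#' @export
detect_peaks <- function(spectrum,
                         min_prominence = 0.01 * max(spectrum$intensity)) {
  y <- spectrum$intensity
  x <- spectrum$energy
  n <- length(y)
  empty <- data.frame(position_eV = numeric(0), height = numeric(0),
                      fwhm_eV = numeric(0))
  if (n < 3) return(empty)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                  y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(cand) == 0) return(empty)
  keep <- vapply(cand, function(i) {
    # walk out until a higher point; key saddle = min along the walk
    left <- y[seq_len(i - 1)]
    hleft <- which(left > y[i])
    lmin <- if (length(hleft)) min(left[(max(hleft)):(i - 1)])
            else min(left)
    right <- y[(i + 1):n]
    hright <- which(right > y[i])
    rmin <- if (length(hright)) min(right[seq_len(min(hright))])
            else min(right)
    (y[i] - max(lmin, rmin)) >= min_prominence
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) return(empty)
  step <- x[2] - x[1]
  out <- lapply(cand, function(i) {
    yl <- y[i - 1]; yc <- y[i]; yr <- y[i + 1]
    denom <- yl - 2 * yc + yr
    dx <- if (denom < 0) 0.5 * (yl - yr) / denom else 0
    dx <- max(min(dx, 0.5), -0.5)
    height <- yc - 0.25 * (yl - yr) * dx
    fwhm <- if (denom < 0)
      2 * sqrt(2 * log(2)) * sqrt(-height * step^2 / denom) else NA_real_
    data.frame(position_eV = x[i] + dx * step, height = height,
               fwhm_eV = fwhm)
  })
  out <- do.call(rbind, out)
  out[order(out$position_eV), , drop = FALSE]
}

#' Estimate the excitation fraction from the bleach plateau
#'
#' Matched-filter estimator: the model difference spectrum per unit
#' excitation fraction (bleached ground state plus excited-state
#' contributions, which partially compensate the bleach) is evaluated from
#' the configured spectra and kinetics at each (delay, energy) cell of the
#' plateau window, and the excitation fraction is the precision-weighted
#' regression of the observed differences on this template. This corrects
#' both for the spectral compensation of the bleach and for the population
#' decay across the plateau.
#'
#' @param map A `difference_map`.
#' @param spectra State spectra as in [true_absorption()], on the map's
#'   energy grid.
#' @param params A [kinetic_params()] describing the kinetics; its `f_exc`
#'   only normalizes the template and does not bias the estimate.
#' @param window Energy window of the bleach region (eV).
#' @param plateau_fs Delay window after the onset and before full recovery.
#' @param gs_reference Conversion from model spectrum units to the map's
#'   normalized-yield units. The default `NULL` self-calibrates it from the
#'   measured UV-off (ground-state) yields in the window, so the estimate is
#'   a pure intensity ratio independent of the detector scale.
#' @return List of class `excitation_estimate` with `estimate`, `se`,
#'   `n_cells`, and `reliable` (`FALSE` when the plateau signal-to-noise is
#'   below 3).
#' @export
estimate_excitation_fraction <- function(map, spectra,
                                         params = kinetic_params(),
                                         window = c(530.5, 533),
                                         plateau_fs = c(500, 3000),
                                         gs_reference = NULL) {
  stopifnot(inherits(map, "difference_map"))
  sel <- map[energy_eV >= window[1] & energy_eV <= window[2] &
               delay_fs >= plateau_fs[1] & delay_fs <= plateau_fs[2] &
               is.finite(se) & se > 0]
  if (nrow(sel) == 0) stop("no valid cells in the plateau/bleach window")
  t_eval <- if (all(is.finite(sel$delay_mean_fs))) sel$delay_mean_fs
            else sel$delay_fs
  pop <- model_populations(params, t_eval)
  idx <- match(round(sel$energy_eV, 6), round(spectra$GS$energy, 6))
  if (anyNA(idx)) stop("map energies not on the spectral model grid")
  if (is.null(gs_reference)) {
    gs <- spectra$GS$intensity[idx]
    gs_reference <- sum(sel$gs_yield * gs) / sum(gs^2)
  }
  tmpl <- gs_reference *
    (-pop$gs_deficit * spectra$GS$intensity[idx] +
       pop$pipi * spectra$pipi$intensity[idx] +
       (pop$npi1 + pop$npi2) * spectra$npi$intensity[idx]) /
    params$f_exc
  wts <- 1 / sel$se^2
  denom <- sum(tmpl^2 * wts)
  est <- sum(sel$diff * tmpl * wts) / denom
  se <- sqrt(1 / denom)
  structure(list(estimate = est, se = se, n_cells = nrow(sel),
                 gs_reference = gs_reference,
                 reliable = is.finite(est) && abs(est) / se >= 3),
            class = "excitation_estimate")
}

#' @export
print.excitation_estimate <- function(x, ...) {
  cat(sprintf("excitation fraction: %.4f +/- %.4f (%d cells%s)\n",
              x$estimate, x$se, x$n_cells,
              if (x$reliable) "" else "; UNRELIABLE, plateau SNR < 3"))
  invisible(x)
}
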