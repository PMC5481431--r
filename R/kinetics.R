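# Stable complementary-error-function helpers built on the accurate log tail
# of pnorm: erfc(x) = 2 pnorm(-sqrt(2) x), erfcx(x) = exp(x^2) erfc(x).
.erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
.erfcx <- function(x) exp(x^2 + log(2) + stats::pnorm(-sqrt(2) * x,
                                                      log.p = TRUE))

# Convolution of the causal exponential exp(-k*d)*theta(d) with a normalized
# Gaussian of width sigma:
#   F(d) = 1/2 exp(k^2 s^2/2 - k d) erfc((k s^2 - d)/(sqrt(2) s)).
# Evaluated via the scaled erfcx branch where the exponent would overflow
# (using a - b^2 = -d^2/(2 s^2) with a, b as below).
.Fk <- function(d, k, sigma) {
  if (sigma == 0) return(ifelse(d >= 0, exp(-k * d), 0))
  b <- (k * sigma^2 - d) / (sqrt(2) * sigma)
  out <- numeric(length(d))
  neg <- b <= 0
  out[neg] <- 0.5 * exp(k^2 * sigma^2 / 2 - k * d[neg]) * .erfc(b[neg])
  out[!neg] <- 0.5 * .erfcx(b[!neg]) * exp(-d[!neg]^2 / (2 * sigma^2))
  out
}

# dF/dk and d2F/dk2, needed for the confluent (near-equal-rate) limits.
.Fp <- function(d, k, sigma) {
  if (sigma == 0) return(-d * .Fk(d, k, 0))
  -((d - k * sigma^2) * .Fk(d, k, sigma) +
      sigma^2 * stats::dnorm(d, 0, sigma))
}
.Fpp <- function(d, k, sigma) {
  if (sigma == 0) return(d^2 * .Fk(d, k, 0))
  sigma^2 * .Fk(d, k, sigma) - (d - k * sigma^2) * .Fp(d, k, sigma)
}

.rel_close <- function(a, b, tol = 1e-6) abs(a - b) <= tol * max(abs(a), abs(b))

# Compartment fractions of a sequential first-order chain A -> B -> C -> final
# for unit delta excitation at d = 0, optionally convolved with a Gaussian
# instrument response of width sigma. The Bateman amplitudes are divided
# differences of the exponential kernel over the rate nodes; nearly equal
# rates (relative difference < 1e-6) are collapsed onto their mean node and
# evaluated with the analytic confluent limit, so no division can blow up.
.chain_fractions <- function(d, k1, k2, k3, sigma = 0, tol = 1e-6) {
  stopifnot(k1 > 0, k2 > 0, k3 > 0, sigma >= 0)
  f  <- function(k) .Fk(d, k, sigma)
  fp <- function(k) .Fp(d, k, sigma)

  A <- f(k1)

  # B = -k1 * f[k1, k2]  (first divided difference of the kernel)
  B <- if (.rel_close(k1, k2, tol)) -k1 * fp((k1 + k2) / 2)
       else k1 * (f(k1) - f(k2)) / (k2 - k1)

  # C = k1 k2 * f[k1, k2, k3] (second divided difference, confluent-aware)
  g12 <- .rel_close(k1, k2, tol); g13 <- .rel_close(k1, k3, tol)
  g23 <- .rel_close(k2, k3, tol)
  dd3 <- if (g12 + g13 + g23 >= 2) {
    km <- (k1 + k2 + k3) / 3
    .Fpp(d, km, sigma) / 2
  } else if (g12 || g13 || g23) {
    if (g12)      { ka <- (k1 + k2) / 2; kc <- k3 }
    else if (g13) { ka <- (k1 + k3) / 2; kc <- k2 }
    else          { ka <- (k2 + k3) / 2; kc <- k1 }
    ((f(kc) - f(ka)) / (kc - ka) - fp(ka)) / (kc - ka)
  } else {
    f(k1) / ((k1 - k2) * (k1 - k3)) +
      f(k2) / ((k2 - k1) * (k2 - k3)) +
      f(k3) / ((k3 - k1) * (k3 - k2))
  }
  C <- k1 * k2 * dd3

  S <- if (sigma == 0) as.numeric(d >= 0) else stats::pnorm(d / sigma)
  list(A = A, B = B, C = C, final = S - A - B - C)
}

#' Analytic sequential-chain (Bateman) populations
#'
#' Compartment fractions of the first-order chain A -> B -> C -> final for a
#' delta excitation at `t0`: `A = exp(-k1 (t - t0))` and the standard
#' sums-of-exponentials solutions for B and C, with `final = 1 - A - B - C`.
#' All fractions are 0 before `t0`. Nearly degenerate rates are handled by
#' the analytic equal-rate limit (see [model_populations()] for details).
#'
#' @param t Times in fs.
#' @param t0 Excitation time in fs.
#' @param k1,k2,k3 Rates in 1/fs (> 0).
#' @return data.frame with columns `time_fs`, `A`, `B`, `C`, `final`.
#' @export
bateman_chain <- function(t, t0, k1, k2, k3) {
  fr <- .chain_fractions(t - t0, k1, k2, k3, sigma = 0)
  data.frame(time_fs = t, A = fr$A, B = fr$B, C = fr$C, final = fr$final)
}

#' Gaussian-IRF-convolved causal exponential
#'
#' Closed form for the convolution of `exp(-k (t - t0)) * theta(t - t0)`
#' with a normalized Gaussian of standard deviation `sigma`:
#' `1/2 exp(k^2 sigma^2 / 2 - k (t - t0)) erfc((k sigma^2 - (t - t0)) /
#' (sqrt(2) sigma))`, evaluated with the scaled complementary error function
#' where the plain exponent would overflow. With `sigma = 0` it reduces to
#' the step exponential.
#'
#' @param t Times (fs).
#' @param t0 Step position (fs).
#' @param k Decay rate (1/fs, > 0).
#' @param sigma Gaussian IRF standard deviation (fs, >= 0).
#' @return Numeric vector, smooth in `t`.
#' @export
irf_convolve_exp <- function(t, t0, k, sigma) {
  stopifnot(k > 0, sigma >= 0)
  .Fk(t - t0, k, sigma)
}

#' Combined Gaussian instrument response
#'
#' Quadrature sum of the pump and probe Gaussian FWHMs; with the 70 fs pump
#' and 70 fs probe of the experiment this is 99.0 fs.
#'
#' @param pump_fwhm,probe_fwhm Pulse durations (FWHM, fs, >= 0).
#' @return Combined IRF FWHM in fs.
#' @export
combined_irf <- function(pump_fwhm = 70, probe_fwhm = 70) {
  stopifnot(pump_fwhm >= 0, probe_fwhm >= 0)
  sqrt(pump_fwhm^2 + probe_fwhm^2)
}

#' Kinetic-model parameters
#'
#' Parameters of the sequential relaxation model pi-pi* -> n-pi*(1) ->
#' n-pi*(2) -> final, excited at `t0` by a delta pulse subsequently convolved
#' with the Gaussian instrument response. Defaults are the study's anchor
#' values: a 60 fs internal-conversion onset, biexponential n-pi* decay with
#' 1.9 ps and 10.5 ps, 13% excitation, a 40:1 n-pi*:pi-pi* probe
#' cross-section ratio at the 526.4 eV resonance, and full ground-state
#' recovery from the final channel.
#'
#' @param t0_fs Time zero (fs).
#' @param irf_fwhm_fs Gaussian IRF FWHM (fs, > 0); default
#'   `combined_irf(70, 70)`.
#' @param tau1_fs pi-pi* -> n-pi*(1) lifetime (fs, > 0): the onset delay.
#' @param tau2_ps n-pi*(1) -> n-pi*(2) lifetime (ps, > 0).
#' @param tau3_ps n-pi*(2) -> final lifetime (ps, > 0).
#' @param f_exc Initially excited fraction in [0, 1].
#' @param w_pipi,w_npi1,w_npi2 Relative probe cross-sections of the
#'   compartments at the excited-state region of interest.
#' @param phi_recovery Fraction of the final channel that returns to the
#'   ground state, in [0, 1].
#' @return A named list of class `kinetic_params`.
#' @export
kinetic_params <- function(t0_fs = 0, irf_fwhm_fs = combined_irf(70, 70),
                           tau1_fs = 60, tau2_ps = 1.9, tau3_ps = 10.5,
                           f_exc = 0.13, w_pipi = 1 / 40, w_npi1 = 1,
                           w_npi2 = 1, phi_recovery = 1) {
  p <- list(t0_fs = t0_fs, irf_fwhm_fs = irf_fwhm_fs, tau1_fs = tau1_fs,
            tau2_ps = tau2_ps, tau3_ps = tau3_ps, f_exc = f_exc,
            w_pipi = w_pipi, w_npi1 = w_npi1, w_npi2 = w_npi2,
            phi_recovery = phi_recovery)
  stopifnot(p$irf_fwhm_fs > 0, p$tau1_fs > 0, p$tau2_ps > 0, p$tau3_ps > 0,
            p$f_exc >= 0, p$f_exc <= 1, p$phi_recovery >= 0,
            p$phi_recovery <= 1, p$w_pipi >= 0, p$w_npi1 >= 0, p$w_npi2 >= 0)
  class(p) <- "kinetic_params"
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' IRF-convolved model populations
#'
#' Evaluates the sequential-chain populations with every Bateman exponential
#' term replaced by its closed-form Gaussian-IRF convolution (valid by
#' linearity of the convolution). Populations are absolute fractions of all
#' molecules (i.e. scaled by `f_exc`). The ground-state deficit is
#' `pipi + npi1 + npi2 + final * (1 - phi_recovery)`: molecules still in the
#' excited chain plus the non-recovered part of the final channel.
#'
#' @param params A [kinetic_params()].
#' @param times Times in fs.
#' @return data.frame of class `population_trace` with columns `time_fs`,
#'   `pipi`, `npi1`, `npi2`, `final`, `gs_deficit`.
#' @export
model_populations <- function(params, times) {
  stopifnot(inherits(params, "kinetic_params"))
  sigma <- .fwhm_to_sigma(params$irf_fwhm_fs)
  fr <- .chain_fractions(times - params$t0_fs,
                         1 / params$tau1_fs,
                         1 / (params$tau2_ps * 1000),
                         1 / (params$tau3_ps * 1000),
                         sigma)
  fe <- params$f_exc
  out <- data.frame(time_fs = times,
                    pipi  = fe * fr$A,
                    npi1  = fe * fr$B,
                    npi2  = fe * fr$C,
                    final = fe * fr$final)
  out$gs_deficit <- out$pipi + out$npi1 + out$npi2 +
    out$final * (1 - params$phi_recovery)
  class(out) <- c("population_trace", "data.frame")
  out
}

#' Model signal in a spectral region of interest
#'
#' Two regions of interest are defined: `excited_526`, the background-free
#' excited-state resonance, whose signal is the cross-section-weighted sum
#' of the excited compartments; and `bleach_pi`, the ground-state bleach at
#' the pi* resonances, whose native sign is negative.
#'
#' @param params A [kinetic_params()].
#' @param times Times in fs.
#' @param roi_kind `"excited_526"` or `"bleach_pi"`.
#' @param amplitude Overall scale factor (arbitrary units).
#' @return Numeric model trace.
#' @export
roi_signal <- function(params, times,
                       roi_kind = c("excited_526", "bleach_pi"),
                       amplitude = 1) {
  roi_kind <- match.arg(roi_kind)
  pop <- model_populations(params, times)
  if (roi_kind == "excited_526")
    amplitude * (params$w_pipi * pop$pipi + params$w_npi1 * pop$npi1 +
                   params$w_npi2 * pop$npi2)
  else
    -amplitude * pop$gs_deficit
}
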