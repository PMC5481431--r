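#' Photon-energy grid
#'
#' @param start,stop Grid limits in eV (`start < stop`). Defaults cover the
#'   oxygen K-edge scan range 520-550 eV.
#' @param step Grid step in eV (> 0).
#' @return Numeric vector of photon energies.
#' @export
energy_grid <- function(start = 520, stop = 550, step = 0.5) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            start < stop, step > 0)
  seq(start, stop, by = step)
}

.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Construct a model NEXAFS spectrum object
#'
#' @param energy Photon-energy grid (eV), strictly increasing.
#' @param intensity Non-negative intensity on the grid.
#' @param state State label recorded as provenance.
#' @param fwhm Broadening FWHM (eV) recorded as provenance (`NA` if not
#'   applicable).
#' @return Object of class `nexafs_spectrum` (a data.frame with columns
#'   `energy`, `intensity`).
#' @export
nexafs_spectrum <- function(energy, intensity, state = "custom", fwhm = NA) {
  stopifnot(length(energy) == length(intensity), !is.unsorted(energy))
  if (any(intensity < -1e-12))
    stop("spectrum intensity must be non-negative")
  out <- data.frame(energy = energy, intensity = pmax(intensity, 0))
  attr(out, "state") <- state
  attr(out, "fwhm") <- fwhm
  class(out) <- c("nexafs_spectrum", "data.frame")
  out
}

#' @export
print.nexafs_spectrum <- function(x, ...) {
  cat(sprintf(
    "<nexafs_spectrum> state=%s, %d points, %.4g-%.4g eV, max=%.4g\n",
    attr(x, "state"), nrow(x), min(x$energy), max(x$energy),
    if (nrow(x)) max(x$intensity) else NA_real_))
  invisible(x)
}

#' Gaussian broadening of stick lines
#'
#' Each stick line contributes a normalized Gaussian centred at its
#' (offset-corrected) energy with area equal to its oscillator strength, so
#' the integrated spectrum equals the summed strengths (area-per-unit-strength
#' constant fixed to 1). Broadening is linear in the line list.
#'
#' @param sticks A [stick_spectrum()].
#' @param fwhm Gaussian full width at half maximum in eV (> 0). The default
#'   0.7 eV exceeds the < 0.5 eV instrumental resolution combined with
#'   lifetime broadening.
#' @param grid Photon-energy grid from [energy_grid()].
#' @return A [nexafs_spectrum()] on `grid`.
#' @examples
#' g <- energy_grid(524, 529, 0.01)
#' s <- gaussian_broaden(stick_spectrum(526.4, 1), fwhm = 0.5, grid = g)
#' g[which.max(s$intensity)]  # 526.4
#' @export
gaussian_broaden <- function(sticks, fwhm = 0.7, grid = energy_grid()) {
  stopifnot(inherits(sticks, "stick_spectrum"))
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0)
    stop("fwhm must be a single positive value (eV)")
  if (nrow(sticks) == 0) {
    warning("empty stick list: returning an identically zero spectrum")
    return(nexafs_spectrum(grid, rep(0, length(grid)),
                           state = attr(sticks, "state"), fwhm = fwhm))
  }
  sigma <- .fwhm_to_sigma(fwhm)
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(sticks)))
    y <- y + sticks$strength[i] * stats::dnorm(grid, sticks$energy[i], sigma)
  nexafs_spectrum(grid, y, state = attr(sticks, "state"), fwhm = fwhm)
}

#' Ionization-edge step
#'
#' The smooth K-edge ionization onset is modelled as a cumulative-Gaussian
#' step: zero far below the edge, `amplitude` far above, half-rise exactly at
#' `edge_energy`.
#'
#' @param edge_energy Edge position in eV (ground-state default 537 eV).
#' @param edge_width 10-90% rise width in eV (> 0).
#' @param amplitude Step height in spectrum units (>= 0).
#' @return Object of class `edge_step`.
#' @export
edge_step <- function(edge_energy = 537, edge_width = 2, amplitude = 0.35) {
  stopifnot(edge_width > 0, amplitude >= 0)
  structure(list(edge_energy = edge_energy, edge_width = edge_width,
                 amplitude = amplitude), class = "edge_step")
}

# 10-90 width of a cumulative Gaussian is (z90 - z10) = 2.5631 sigma
.edge_sigma <- function(edge) edge$edge_width /
  (stats::qnorm(0.9) - stats::qnorm(0.1))

#' Evaluate an ionization-edge profile on a grid
#'
#' @param edge An [edge_step()].
#' @param grid Photon-energy grid; must cover `edge_energy`.
#' @return A [nexafs_spectrum()]; monotone non-decreasing.
#' @export
edge_profile <- function(edge, grid = energy_grid()) {
  stopifnot(inherits(edge, "edge_step"))
  if (edge$edge_energy < min(grid) || edge$edge_energy > max(grid))
    stop("grid does not cover the edge energy")
  y <- edge$amplitude * stats::pnorm(grid, edge$edge_energy, .edge_sigma(edge))
  nexafs_spectrum(grid, y, state = "edge", fwhm = NA)
}

#' Half-rise energy of an edge-like profile
#'
#' Locates, by linear interpolation, the energy at which a monotone profile
#' first reaches half of its asymptotic amplitude.
#'
#' @param spectrum A [nexafs_spectrum()] (typically from [edge_profile()]).
#' @param amplitude Asymptotic amplitude; defaults to the maximum intensity.
#' @return Energy in eV.
#' @export
edge_half_rise <- function(spectrum, amplitude = max(spectrum$intensity)) {
  y <- spectrum$intensity - amplitude / 2
  i <- which(y[-1] >= 0 & y[-length(y)] < 0)[1]
  if (is.na(i)) stop("profile does not cross half amplitude on the grid")
  e1 <- spectrum$energy[i]; e2 <- spectrum$energy[i + 1]
  e1 + (e2 - e1) * (-y[i]) / (y[i + 1] - y[i])
}

#' Spectral-model configuration
#'
#' Collects the tunable choices of the spectral model: broadening width, the
#' ground-state edge, the (qualitative, configurable) redshift of the
#' excited-state edges, and whether edges are included at all. Edges can be
#' switched off to mimic simulated spectra in which ionization continua are
#' not modelled.
#'
#' @param fwhm Broadening FWHM in eV.
#' @param edge Ground-state [edge_step()].
#' @param edge_redshift Redshift (eV) of excited-state edges relative to the
#'   ground state.
#' @param include_edge Logical: add the edge step to state spectra.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(fwhm = 0.7, edge = edge_step(),
                            edge_redshift = 1.0, include_edge = TRUE) {
  stopifnot(fwhm > 0, inherits(edge, "edge_step"), edge_redshift >= 0)
  structure(list(fwhm = fwhm, edge = edge, edge_redshift = edge_redshift,
                 include_edge = include_edge), class = "spectral_config")
}

#' Model spectrum of one electronic state
#'
#' Broadens the packaged stick fixture for `state` and, unless disabled, adds
#' the ionization-edge step (redshifted for excited states, since the
#' excited-state spectrum shifts to lower photon energy).
#'
#' @param state One of `"GS"`, `"pipi_FC"`, `"pipi_saddle"`, `"npi_min"`.
#' @param fwhm Broadening FWHM (eV); defaults to the config value.
#' @param grid Photon-energy grid.
#' @param config A [spectral_config()].
#' @param include_edge Override of `config$include_edge`.
#' @return A [nexafs_spectrum()].
#' @export
state_spectrum <- function(state, fwhm = NULL, grid = energy_grid(),
                           config = spectral_config(),
                           include_edge = config$include_edge) {
  sticks <- state_sticks(state)   # errors on unknown label
  if (is.null(fwhm)) fwhm <- config$fwhm
  sp <- gaussian_broaden(sticks, fwhm = fwhm, grid = grid)
  if (include_edge) {
    e <- config$edge
    if (state != "GS")
      e <- edge_step(e$edge_energy - config$edge_redshift, e$edge_width,
                     e$amplitude)
    # evaluated directly so restricted scan grids below the edge still work
    sp$intensity <- sp$intensity +
      e$amplitude * stats::pnorm(grid, e$edge_energy, .edge_sigma(e))
  }
  attr(sp, "state") <- state
  sp
}

#' Default state spectra for the transient model
#'
#' The compartments of the kinetic model map onto three spectra: the ground
#' state, the pi-pi* state (Franck-Condon fixture) and the n-pi* state (both
#' n-pi* compartments share the same spectrum).
#'
#' @inheritParams state_spectrum
#' @return Named list with elements `GS`, `pipi`, `npi`.
#' @export
default_spectra <- function(grid = energy_grid(), config = spectral_config()) {
  list(GS   = state_spectrum("GS", grid = grid, config = config),
       pipi = state_spectrum("pipi_FC", grid = grid, config = config),
       npi  = state_spectrum("npi_min", grid = grid, config = config))
}

#' Population-weighted superposition of state spectra
#'
#' The transient spectrum is the ground-state spectrum weakened by the
#' fraction of molecules no longer in the ground state, plus the excited-state
#' spectra weighted by their populations:
#' `total = (1 - depleted) * GS + sum_i p_i * S_i`, where
#' `depleted = sum(populations) + dark` (dark molecules absorb nothing).
#'
#' @param populations Named numeric vector of state populations (absolute
#'   fractions of all molecules); names must match excited entries of
#'   `spectra`.
#' @param f_exc Initially excited fraction; `sum(populations) + dark` must
#'   not exceed it.
#' @param spectra Named list of [nexafs_spectrum()] including `GS`.
#' @param dark Population in dark (non-absorbing) channels.
#' @return A [nexafs_spectrum()] of the mixture.
#' @export
mix_spectra <- function(populations, f_exc, spectra, dark = 0) {
  stopifnot(is.numeric(populations), is.numeric(f_exc), f_exc >= 0,
            f_exc <= 1, dark >= 0, "GS" %in% names(spectra))
  if (length(populations) > 0 && is.null(names(populations)))
    stop("populations must be named after entries of `spectra`")
  if (any(populations < 0)) stop("populations must be >= 0")
  depleted <- sum(populations) + dark
  if (depleted > f_exc + 1e-9)
    stop("population sum exceeds the excitation fraction f_exc")
  gs <- spectra$GS
  y <- (1 - depleted) * gs$intensity
  for (nm in names(populations)) {
    s <- spectra[[nm]]
    if (is.null(s)) stop("no spectrum supplied for state '", nm, "'")
    if (!isTRUE(all.equal(s$energy, gs$energy)))
      stop("state spectra must share one energy grid")
    y <- y + populations[[nm]] * s$intensity
  }
  nexafs_spectrum(gs$energy, y, state = "mixture", fwhm = attr(gs, "fwhm"))
}

#' Pointwise difference spectrum (pumped minus unpumped)
#'
#' @param total,gs Two [nexafs_spectrum()] on identical grids.
#' @return data.frame with columns `energy` and `difference` (signed, no
#'   clipping of negative values).
#' @export
difference_spectrum <- function(total, gs) {
  stopifnot(inherits(total, "nexafs_spectrum"), inherits(gs, "nexafs_spectrum"))
  if (!isTRUE(all.equal(total$energy, gs$energy)))
    stop("difference_spectrum requires identical energy grids")
  data.frame(energy = total$energy,
             difference = total$intensity - gs$intensity)
}
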