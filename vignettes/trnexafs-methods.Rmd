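---
title: "Models and methods behind trnexafs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trnexafs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnexafs)
```

`trnexafs` is a simulation and analysis chain for femtosecond time-resolved
near-edge X-ray absorption (TR-NEXAFS) pump–probe experiments of the kind
performed on gas-phase thymine at a free-electron laser (FEL): a UV pump
promotes a fraction of the molecules to the bright pi-pi* state, and a
tunable soft X-ray probe measures the oxygen K-edge absorption (via the
integrated Auger electron yield) as a function of pump–probe delay. Because
the n-pi* excited state carries an oxygen-localized core-to-hole resonance
that the pi-pi* state lacks (a roughly 40:1 oscillator-strength ratio), the
appearance of a background-free feature below the pi* resonances is a
direct, electronic-structure-specific clock for pi-pi*/n-pi* internal
conversion. This vignette documents the models, the synthetic-data
generator, the reduction pipeline, the fitting machinery, and the numerical
choices, in that order.

## Spectral model

Each electronic state is represented by a *stick spectrum* — discrete
(transition energy, oscillator strength) lines — broadened with normalized
Gaussians so that every line contributes area equal to its strength
(`gaussian_broaden()`). The ionization continuum is a cumulative-Gaussian
step (`edge_step()`, `edge_profile()`): half-rise exactly at the edge
energy, parameterized by its 10–90% rise width. Excited-state edges are
redshifted relative to the ground state by a configurable amount (default
1.0 eV; only the existence and direction of the shift are established, not
its magnitude).

The packaged stick fixtures are **synthetic stand-ins**, not
electronic-structure output. They are constructed so that the broadened
(FWHM 0.7 eV) observables reproduce the anchor values of the system: two
ground-state pi* maxima at 531.4 and 532.2 eV (stick energies 531.3837 and
532.2210 eV, solved numerically so that the overlapping Gaussians peak at
the printed positions), the lowest excited-state resonance at 526.4 eV in
all three excited-state fixtures, a 40:1 strength ratio between the lowest
n-pi* and pi-pi* lines, and a ground-state edge at 537.0 eV. The n-pi*
fixture additionally carries resonances near the pi* region so that, as
observed experimentally, the ground-state bleach there is largely (here
about 80%) compensated by excited-state absorption. Conclusions that depend
on details of the real spectra beyond these anchored observables cannot be
drawn from the fixtures.

The default broadening of 0.7 eV exceeds the instrument's < 0.5 eV
resolution combined with lifetime broadening; it is configurable. A
relativistic correction to core-excitation energies (0.1–0.3 eV) is *not*
applied; fixtures are defined post-correction. Because simulated spectra
are sometimes presented without continua, `state_spectrum()` exposes an
`include_edge` switch.

Transient spectra are population mixtures (`mix_spectra()`):

$$S(E, t) = \bigl(1 - d(t)\bigr)\, S_\mathrm{GS}(E) + \sum_i p_i(t)\, S_i(E),$$

where $d(t)$ — the ground-state deficit — is the summed excited-state
population plus any dark (non-absorbing, non-recovered) population.

## Kinetic model

The relaxation chain is the minimal sequential model reproducing a delayed
onset plus biexponential decay:

$$\text{pi-pi*} \xrightarrow{\tau_1} \text{n-pi*}_1 \xrightarrow{\tau_2}
  \text{n-pi*}_2 \xrightarrow{\tau_3} \text{final},$$

with anchor parameters $\tau_1 = 60$ fs, $\tau_2 = 1.9$ ps,
$\tau_3 = 10.5$ ps, excitation fraction $f_\mathrm{exc} = 0.13$, and probe
weights $w_{\pi\pi^*} = 1/40$, $w_{n\pi^*_1} = w_{n\pi^*_2} = 1$ at the
526.4 eV region of interest. Both n-pi* compartments share the n-pi*
spectrum; the final compartment returns to the ground state with
probability `phi_recovery` (default 1, motivated by the observed bleach
recovery; the competing intersystem-crossing channel can be represented by
lowering it). Whether the original analysis used this exact compartment
count is not documented in the available text; the chain above is this
package's definition, and all recovery results are stated against its own
generator.

Excitation is treated as a delta pulse at $t_0$ convolved with the combined
Gaussian instrument response (`combined_irf()`, quadrature sum of the 70 fs
pump and probe: 99.0 fs FWHM) — equivalent to finite-pulse pumping for
linear kinetics. The chain populations are Bateman sums of exponentials,
and each exponential term convolved with the Gaussian IRF has the closed
form

$$F(t) = \tfrac{1}{2}\, e^{k^2\sigma^2/2 - k\Delta}\,
  \mathrm{erfc}\!\left(\frac{k\sigma^2 - \Delta}{\sqrt{2}\,\sigma}\right),
  \qquad \Delta = t - t_0,$$

evaluated through the scaled complementary error function
($\mathrm{erfcx}$, built on the accurate log tail of `pnorm`) wherever the
plain exponent would overflow (`irf_convolve_exp()`).

**Degenerate rates.** The Bateman amplitudes are divided differences of the
exponential kernel over the rate nodes. When two (or three) rates agree to
better than a relative $10^{-6}$, the nodes are collapsed onto their mean
and the confluent limit (first/second kernel derivative) is used. Using the
group *mean* matters: it cancels the first-order error in the rate
splitting, so the two branches agree to ~$10^{-9}$ at the threshold rather
than ~$10^{-5}$. Division by a rate difference therefore never blows up.

## Synthetic data generator

`generate_shots()` emulates the statistical structure of FEL acquisition,
one table row per shot:

* **Timing jitter**: Gaussian, $\sigma = 100$ fs (a typical FEL value; the
  experiment measures jitter per shot but its magnitude is not printed).
  The value is chosen to exceed the 50 fs bin width, so resorting is
  actually exercised. The cross-correlator measurement is taken as exact:
  the true delay is `nominal + jitter`, and `jitter_correct()` recovers it.
* **Intensity**: Gamma-distributed with mean 1 and shape 5 (~45% rms),
  standing in for "strongly fluctuating" pulse energies.
* **UV blocking**: Bernoulli(0.5) per shot.
* **Counting noise**: `auger_yield ~ Poisson(intensity × absorption ×
  mean_counts / reference)`, with 50 mean counts at the strongest
  ground-state resonance and the yield proportional to the absorption
  cross-section.

The defaults scan 520–550 eV in 0.5 eV steps over delays from −200 fs to
20 ps (25 fs spacing through the onset, 100–200 fs through the picosecond
decay), 800 shots per setting (~5.3 M shots). The delay schedule and shot
count were set, once, so that the joint kinetic fit on a default dataset
returns decay-constant uncertainties comparable to the reported
experimental ones (~0.1 ps on $\tau_2$, ~0.2 ps on $\tau_3$); with both
regions of interest pinning $t_0$ jointly, the synthetic onset delay is
then determined to ~2.4 fs, considerably tighter than the reported ±30 fs —
recovery results on $\tau_1$ should be read with that in mind. Features of
real data *not* emulated: drifting (non-stationary) timing offsets,
correlated intensity–pointing fluctuations, detector saturation and
background electrons, UV-induced photofragmentation, and spectrometer
lineshape effects. Passing tests therefore validate the reduction and
fitting chain under the stated statistical model, not under every
instrumental pathology.

`fluence_scan()` scales $f_\mathrm{exc}$ linearly with pump fluence by
construction (no saturation model) and exists to verify the linear-regime
bookkeeping end to end.

## Resorting and binning

`bin_and_difference()` implements the reduction: shots are sorted by
jitter-corrected delay into bins of ≥ 50 fs width (edges anchored at zero
delay) and into quantile-based X-ray intensity bins (default 4); per
(delay bin, energy, intensity bin) cell the mean intensity-normalized
yield of UV-on shots minus UV-off shots forms a difference, and differences
are averaged *unweighted* across intensity bins with errors propagated in
quadrature. Normalizing each shot by its measured intensity is the simplest
unbiased choice for a yield proportional to intensity; the map is invariant
under a common rescaling of yields and intensities.

Three robustness choices deserve explanation:

* **Error floors.** The variance of a cell's mean is the sample variance
  floored by the Poisson counting expectation
  $\hat\lambda\,\overline{1/I}/n$ with the zero-protected pooled rate
  $\hat\lambda = (\sum y + 1/2)/\sum I$. In the background-free region
  entire cells can record zero counts; their sample variance is zero, and
  without the floor such cells would enter the weighted fit with infinite
  weight.
* **Missing means missing.** Cells lacking a UV-on or UV-off half (or with
  fewer than `min_shots_per_cell = 5` shots in either half) are flagged and
  excluded, never treated as zero.
* **Complete windows only.** `integrate_roi()` uses a delay bin only when
  *every* window energy is valid there; a partially covered window would
  bias the integral toward zero. Trace error bars are standard errors of
  the mean, combined in quadrature across the window.

Each delay bin records the mean and variance of the corrected delays of its
shots; both are carried into the traces for use by the fit.
`select_snr_roi()` scores candidate windows by the precision-weighted mean
signal over a plateau window divided by its standard error, with ties
broken toward the lower energy bound.

## Fitting

`fit_kinetics()` minimizes weighted ($1/\mathrm{SE}^2$) residuals jointly
over the excited-state and bleach traces with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`), multi-started (default 5 starts: the initial guess
plus log-uniform ±50% perturbations of the positive parameters and ±50 fs
on $t_0$, under fixed sub-seeds) to avoid local minima — with these data
the main local trap is a collapse of $\tau_2$ toward zero that mimics a
single-exponential decay. Standard errors come from the finite-difference
Jacobian covariance scaled by the reduced chi-square; non-convergence (or a
singular covariance) is flagged and no values are reported as valid. The
default free set is $t_0$, $\tau_1$, $\tau_2$, $\tau_3$ and the two trace
amplitudes; the IRF stays fixed at the known pulse durations.

The model value for a binned point is the second-order bin average
$m(\bar t) + \tfrac{1}{2}\mathrm{Var}(t)\, m''(\bar t)$ using the recorded
within-bin delay variance. This matters: without the curvature term the
50 fs binning acts as unmodelled extra smearing and biases the recovered
onset delay high by about 4–5 fs — twice its standard error under default
statistics.

`detect_peaks()` finds local maxima above a prominence threshold (default
1% of the spectrum maximum) and refines positions by three-point parabolic
interpolation; it is translation-equivariant and reports Gaussian-model
widths from the local curvature.

`estimate_excitation_fraction()` generalizes a plateau-depth ratio into a
matched filter: the model difference per unit excitation fraction
(bleached ground state plus the partially compensating excited-state
absorption, evolved over the plateau with the kinetic model) is regressed
against the observed map cells with precision weights. The intensity scale
is self-calibrated from the measured UV-off yields (`gs_yield`), making
the estimate a pure intensity ratio; a fixed conversion can be supplied via
`gs_reference` instead. Estimates with plateau signal-to-noise below 3 are
flagged unreliable.

## Numerical and degenerate-input choices

* Empty stick lists broaden to an all-zero spectrum with a warning;
  non-positive FWHM, unknown state labels, mismatched grids, populations
  exceeding $f_\mathrm{exc}$, and empty ROI windows are rejected.
* Shots without a jitter measurement are dropped and counted; shots beyond
  ±3 (empirical) jitter SDs outside the nominal schedule are dropped and
  counted.
* The near-degenerate rate threshold is a relative $10^{-6}$; the fit
  bounds keep lifetimes positive, $f_\mathrm{exc} \in [10^{-4}, 1]$ and
  `phi_recovery` $\in [0,1]$.
* All randomness flows from explicit integer seeds (generator seed in the
  config; fixed sub-seeds for multi-start perturbations), so every run is
  exactly reproducible.

## Problem sizes used by the packaged checks

The end-to-end checks run the full default configuration (~5.3 M shots,
~400 delay bins, fits on ~390-point traces; tens of seconds). Unit and
property tests use a reduced scan (20 energies covering both regions of
interest, 27 delays, 250 shots per setting) chosen so that a 20-replicate
parameter-recovery study — median recovery within one standard error and
90%+ nominal-95% coverage — completes in well under a minute.

## Known limitations

* The stick fixtures pin only the printed observables; real spectra have
  more structure (vibronic envelopes, additional Rydberg/valence states).
* The compartment model is a definition, not a derivation; lifetimes
  recovered from data generated by a different mechanism (e.g. parallel
  channels) would be effective parameters.
* The reported onset-delay uncertainty is a fit standard error; systematic
  timing-calibration uncertainty of a real beamline is not modelled.
* Absolute cross-sections (Mbarn) are out of scope; all intensities are
  relative.
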