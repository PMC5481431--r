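#' Binning specification for the resorting step
#'
#' Shots are resorted by jitter-corrected delay into bins of at least 50 fs
#' width and, in parallel, into several quantile-based X-ray intensity bins;
#' difference spectra formed per intensity bin are then averaged unweighted.
#'
#' @param delay_bin_width Delay bin width in fs (>= 50).
#' @param n_intensity_bins Number of quantile intensity bins (>= 1,
#'   default 4).
#' @param min_shots_per_cell Minimum shots required in each of the UV-on and
#'   UV-off halves of a cell for it to be valid (>= 2, so a standard error
#'   exists).
#' @return A list of class `binning_spec`.
#' @export
binning_spec <- function(delay_bin_width = 50, n_intensity_bins = 4,
                         min_shots_per_cell = 5) {
  stopifnot(delay_bin_width >= 50, n_intensity_bins >= 1,
            min_shots_per_cell >= 2)
  structure(list(delay_bin_width = delay_bin_width,
                 n_intensity_bins = as.integer(n_intensity_bins),
                 min_shots_per_cell = as.integer(min_shots_per_cell)),
            class = "binning_spec")
}

#' Jitter-correct shot delays
#'
#' Adds `corrected_delay = nominal_delay + measured_jitter` (sign convention:
#' positive jitter means the X-ray probe arrives later relative to the UV
#' pump). Shots without a jitter measurement cannot be resorted and are
#' dropped; the count is kept in the `dropped_shots` attribute.
#'
#' @param shots A `shot_table` from [generate_shots()] or [read_shots()].
#' @return The shot table with a `corrected_delay` column.
#' @export
jitter_correct <- function(shots) {
  stopifnot("measured_jitter" %in% names(shots))
  shots <- data.table::as.data.table(shots)
  dropped <- sum(is.na(shots$measured_jitter))
  if (dropped > 0) {
    message(dropped, " shot(s) without jitter measurement dropped")
    shots <- shots[!is.na(measured_jitter)]
  }
  shots[, corrected_delay := nominal_delay + measured_jitter]
  data.table::setattr(shots, "dropped_shots", dropped)
  data.table::setattr(shots, "class",
                      c("shot_table", class(data.table::data.table())))
  shots[]
}

#' Bin shots and form normalized difference spectra
#'
#' The core data-reduction step. Per (delay bin, photon energy, intensity
#' bin) cell, the mean intensity-normalized yield (`auger_yield /
#' xray_intensity`) of UV-on shots minus that of UV-off shots gives one
#' difference value; cells lacking either half (or with fewer than
#' `min_shots_per_cell` shots in one half) are flagged missing, never
#' silently zero. Differences are then averaged unweighted over intensity
#' bins with standard errors propagated in quadrature.
#'
#' Delay bin edges are anchored at zero delay with the configured width.
#' Shots whose corrected delay falls more than three (empirical) jitter
#' standard deviations outside the nominal schedule are dropped and counted.
#'
#' @param shots A jitter-corrected `shot_table` (see [jitter_correct()]).
#' @param spec A [binning_spec()].
#' @return A `data.table` of class `difference_map` with columns `delay_fs`
#'   (bin center), `delay_mean_fs` (mean corrected delay of the shots in the
#'   bin), `energy_eV`, `diff`, `se`, `gs_yield` / `gs_se` (the UV-off
#'   normalized yield, i.e. the measured ground-state reference spectrum, in
#'   the same units as `diff`), `n_shots`; attributes record the bin width,
#'   energy step, and missing-cell / dropped-shot counters.
#' @export
bin_and_difference <- function(shots, spec = binning_spec()) {
  stopifnot(inherits(spec, "binning_spec"))
  if (!"corrected_delay" %in% names(shots))
    stop("shots are not jitter-corrected; run jitter_correct() first")
  dt <- data.table::as.data.table(shots)

  sd_j <- stats::sd(dt$measured_jitter)
  if (!is.finite(sd_j)) sd_j <- 0
  lo <- min(dt$nominal_delay) - 3 * sd_j
  hi <- max(dt$nominal_delay) + 3 * sd_j
  n0 <- nrow(dt)
  dt <- dt[corrected_delay >= lo & corrected_delay <= hi]
  dropped <- n0 - nrow(dt)

  w <- spec$delay_bin_width
  dt[, delay_bin := floor(corrected_delay / w)]
  if (spec$n_intensity_bins > 1) {
    qs <- stats::quantile(dt$xray_intensity,
                          probs = seq(0, 1,
                                      length.out = spec$n_intensity_bins + 1))
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    dt[, ibin := findInterval(xray_intensity, qs,
                              rightmost.closed = TRUE)]
  } else dt[, ibin := 1L]
  dt[, norm_yield := auger_yield / xray_intensity]

  # Variance of the mean normalized yield: the sample variance, floored by
  # the Poisson counting expectation lambda * E[1/I] / n for Y ~ Poisson
  # with yield proportional to intensity I. The pooled rate estimate
  # lambda = (sum(y) + 1/2) / sum(I) is zero-protected, so cells that
  # happen to record no counts (common in the background-free region) still
  # carry a finite, meaningful error bar instead of an infinite weight.
  cells <- dt[, .(m = mean(norm_yield),
                  se2 = pmax(stats::var(norm_yield) / .N,
                             (sum(auger_yield) + 0.5) / sum(xray_intensity) *
                               mean(1 / xray_intensity) / .N),
                  n = .N),
              by = .(delay_bin, photon_energy, ibin, uv_on)]
  wide <- data.table::dcast(cells, delay_bin + photon_energy + ibin ~ uv_on,
                            value.var = c("m", "se2", "n"))
  for (col in c("m_TRUE", "m_FALSE", "se2_TRUE", "se2_FALSE",
                "n_TRUE", "n_FALSE"))
    if (!col %in% names(wide)) wide[, (col) := NA_real_]
  wide <- wide[!is.na(m_TRUE) & !is.na(m_FALSE) &
                 n_TRUE >= spec$min_shots_per_cell &
                 n_FALSE >= spec$min_shots_per_cell]
  n_cells_in <- nrow(unique(dt[, .(delay_bin, photon_energy, ibin)]))
  missing_cells <- n_cells_in - nrow(wide)

  wide[, `:=`(d = m_TRUE - m_FALSE, se2 = se2_TRUE + se2_FALSE,
              n = n_TRUE + n_FALSE)]
  map <- wide[, .(diff = mean(d),
                  se = sqrt(sum(se2)) / .N,
                  gs_yield = mean(m_FALSE),
                  gs_se = sqrt(sum(se2_FALSE)) / .N,
                  n_shots = sum(n)),
              by = .(delay_bin, energy_eV = photon_energy)]

  centers <- dt[, .(delay_mean_fs = mean(corrected_delay),
                    delay_var_fs2 = stats::var(corrected_delay)),
                by = delay_bin]
  centers[!is.finite(delay_var_fs2), delay_var_fs2 := 0]
  map <- centers[map, on = "delay_bin"]
  map[, delay_fs := (delay_bin + 0.5) * w]
  map[, delay_bin := NULL]
  data.table::setcolorder(map, c("delay_fs", "delay_mean_fs",
                                 "delay_var_fs2", "energy_eV", "diff", "se",
                                 "gs_yield", "gs_se", "n_shots"))
  data.table::setorder(map, delay_fs, energy_eV)

  en <- sort(unique(map$energy_eV))
  data.table::setattr(map, "bin_width", w)
  data.table::setattr(map, "energy_step",
                      if (length(en) > 1) stats::median(diff(en)) else NA_real_)
  data.table::setattr(map, "n_intensity_bins", spec$n_intensity_bins)
  data.table::setattr(map, "missing_cells", missing_cells)
  data.table::setattr(map, "dropped_shots", dropped)
  data.table::setattr(map, "class",
                      c("difference_map", class(data.table::data.table())))
  map[]
}

#' Integrate a difference map over a spectral region of interest
#'
#' Per delay bin, sums the difference values over the energy window weighted
#' by the energy step, with standard errors combined in quadrature. Error
#' bars on the result are the standard error of the mean propagated from the
#' per-cell statistics.
#'
#' @param map A `difference_map` from [bin_and_difference()].
#' @param window Energy interval `c(lo, hi)` in eV; must overlap the energy
#'   axis.
#' @return A `data.table` of class `time_trace` with columns `delay_fs`,
#'   `delay_mean_fs`, `signal`, `se`, `n_shots`; attribute `roi` records the
#'   window.
#' @export
integrate_roi <- function(map, window) {
  stopifnot(inherits(map, "difference_map"), length(window) == 2,
            window[1] < window[2])
  sel <- map[energy_eV >= window[1] & energy_eV <= window[2]]
  if (nrow(sel) == 0)
    stop("ROI window does not overlap the energy axis of the map")
  de <- attr(map, "energy_step")
  if (!is.finite(de)) de <- 1
  # a partially covered window would bias the integral low, so a delay bin
  # contributes only when every window energy present in the map is valid
  n_win <- length(unique(sel$energy_eV))
  tr <- sel[, .(delay_mean_fs = delay_mean_fs[1],
                delay_var_fs2 = delay_var_fs2[1],
                signal = sum(diff) * de,
                se = sqrt(sum(se^2)) * de,
                n_shots = sum(n_shots),
                complete = .N == n_win),
            by = delay_fs]
  tr <- tr[complete == TRUE][, complete := NULL]
  data.table::setorder(tr, delay_fs)
  data.table::setattr(tr, "roi", window)
  data.table::setattr(tr, "class",
                      c("time_trace", class(data.table::data.table())))
  tr[]
}

#' Select the best signal-to-noise region of interest
#'
#' Scores each candidate energy window by the absolute precision-weighted
#' mean of its time trace over a plateau delay window divided by the standard
#' error of that mean, and returns the best window. Ties are broken
#' deterministically towards the lower energy bound.
#'
#' @param map A `difference_map`.
#' @param candidate_windows List of `c(lo, hi)` energy windows (>= 1).
#' @param plateau_fs Delay window over which the signal is scored.
#' @return The winning window, with the per-candidate scores attached as the
#'   `scores` attribute.
#' @export
select_snr_roi <- function(map, candidate_windows,
                           plateau_fs = c(500, 3000)) {
  stopifnot(length(candidate_windows) >= 1)
  if (nrow(map) == 0) stop("difference map has no valid cells")
  scores <- vapply(candidate_windows, function(wdw) {
    tr <- integrate_roi(map, wdw)
    tr <- tr[delay_fs >= plateau_fs[1] & delay_fs <= plateau_fs[2] &
               is.finite(se) & se > 0]
    if (nrow(tr) == 0) return(NA_real_)
    wts <- 1 / tr$se^2
    abs(sum(tr$signal * wts) / sum(wts)) * sqrt(sum(wts))
  }, numeric(1))
  if (all(is.na(scores))) stop("no candidate window has usable cells")
  lower <- vapply(candidate_windows, `[`, numeric(1), 1)
  best <- order(-scores, lower)[1]
  out <- candidate_windows[[best]]
  attr(out, "scores") <- scores
  out
}
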