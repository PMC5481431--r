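#' Default end-to-end configuration
#'
#' Single nested configuration with blocks `experiment`, `kinetics`,
#' `spectra`, `binning`, `rois` and `fit`, all defaulting to the anchor
#' values of the study conditions. Serializable to YAML with
#' [write_config()] / [read_config()].
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    experiment = unclass(experiment_config()),
    kinetics = unclass(kinetic_params()),
    spectra = list(fwhm = 0.7, edge_energy = 537, edge_width = 2,
                   edge_amplitude = 0.35, edge_redshift = 1,
                   include_edge = TRUE),
    binning = list(delay_bin_width = 50, n_intensity_bins = 4,
                   min_shots_per_cell = 5),
    rois = list(excited = c(525, 528), bleach = c(530.5, 533)),
    fit = list(free = .fit_free_default, n_starts = 5, seed = 42)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (blk in names(base))
    if (!is.null(cfg[[blk]]))
      base[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
  base
}

#' @param config A `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Rebuild the typed objects from the plain config blocks
.cfg_experiment <- function(config) do.call(experiment_config,
                                            config$experiment)
.cfg_kinetics <- function(config) do.call(kinetic_params, config$kinetics)
.cfg_spectral <- function(config) {
  s <- config$spectra
  spectral_config(fwhm = s$fwhm,
                  edge = edge_step(s$edge_energy, s$edge_width,
                                   s$edge_amplitude),
                  edge_redshift = s$edge_redshift,
                  include_edge = s$include_edge)
}
.cfg_binning <- function(config) do.call(binning_spec, config$binning)

#' Run the full pipeline: simulate, resort, integrate, fit
#'
#' Executes the four stages in order on one configuration and seed:
#' shot-level simulation, jitter-corrected binning into a difference map,
#' ROI integration into the excited-state and bleach time traces, and the
#' joint kinetic fit. Stage outputs are written under `out_dir` and listed
#' in the returned manifest; the run is idempotent for a fixed config and
#' seed.
#'
#' @param config A `pipeline_config` (or a YAML path).
#' @param seed Optional integer overriding `config$experiment$seed`.
#' @param out_dir Output directory (created if needed).
#' @param write_shots_file Write the (large) shot-level CSV; disable to save
#'   time and disk.
#' @return Object of class `pipeline_run`: the manifest plus in-memory
#'   `map`, `traces`, and `fit`.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = tempfile("trnexafs_run_"),
                         write_shots_file = FALSE) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) config$experiment$seed <- as.integer(seed)

  expcfg <- .cfg_experiment(config)
  params <- .cfg_kinetics(config)
  spcfg <- .cfg_spectral(config)
  spectra <- default_spectra(grid = expcfg$photon_energies, config = spcfg)
  paths <- list()

  message("stage simulate: ", length(expcfg$photon_energies), " energies x ",
          length(expcfg$delay_schedule), " delays x ",
          expcfg$shots_per_setting, " shots")
  shots <- generate_shots(expcfg, params, spectra)
  message("  generated ", nrow(shots), " shots")
  if (write_shots_file) {
    paths$simulate <- file.path(out_dir, "shots.csv")
    write_shots(shots, paths$simulate)
  } else paths$simulate <- NA_character_

  shots <- jitter_correct(shots)
  map <- bin_and_difference(shots, .cfg_binning(config))
  message("stage resort: ", length(unique(map$delay_fs)), " delay bins, ",
          attr(map, "missing_cells"), " missing cells, ",
          attr(map, "dropped_shots"), " shots dropped")
  paths$resort <- file.path(out_dir, "difference_map.csv")
  data.table::fwrite(map, paths$resort)

  traces <- list(excited = integrate_roi(map, config$rois$excited),
                 bleach = integrate_roi(map, config$rois$bleach))
  message("stage traces: excited ", nrow(traces$excited), " points, bleach ",
          nrow(traces$bleach), " points")
  paths$traces <- c(file.path(out_dir, "trace_excited.csv"),
                    file.path(out_dir, "trace_bleach.csv"))
  data.table::fwrite(traces$excited, paths$traces[1])
  data.table::fwrite(traces$bleach, paths$traces[2])

  fit <- fit_kinetics(traces, init = params, free = config$fit$free,
                      n_starts = config$fit$n_starts, seed = config$fit$seed)
  message("stage fit: ", if (fit$convergence) "converged" else "FAILED",
          ", chi2_red = ", signif(fit$chi2_red, 4))
  paths$fit <- file.path(out_dir, "fit_report.json")
  write_fit_report(fit, paths$fit)

  manifest <- structure(list(
    config_hash = rlang::hash(config),
    seed = config$experiment$seed,
    stages = paths,
    counters = list(shots = nrow(shots),
                    dropped_shots = attr(map, "dropped_shots"),
                    missing_cells = attr(map, "missing_cells")),
    package_version = as.character(utils::packageVersion("trnexafs")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(list(manifest = manifest, config = config, map = map,
                 traces = traces, fit = fit, out_dir = out_dir),
            class = "pipeline_run")
}

#' Render report figures for a pipeline run
#'
#' Produces the standard figure set: the false-color difference map, the two
#' ROI traces with standard-error bars and fit curves, the ground-state vs
#' 2 ps model-spectra overlay, and the per-state simulated spectra scaled by
#' the excitation fraction. Figures are written as PDFs under the run's
#' output directory; missing stages are skipped with a warning rather than
#' failing the report.
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @param out_dir Directory for the figure files.
#' @return Named list of ggplot objects, invisibly.
#' @export
render_report <- function(run, out_dir = run$out_dir) {
  stopifnot(inherits(run, "pipeline_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plots <- list()

  if (!is.null(run$map) && nrow(run$map) > 0) {
    plots$difference_map <-
      ggplot2::ggplot(run$map,
                      ggplot2::aes(x = delay_fs / 1000, y = energy_eV,
                                   fill = diff)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                    high = "red3", midpoint = 0) +
      ggplot2::labs(x = "pump-probe delay (ps)", y = "photon energy (eV)",
                    fill = "UV on - off", title = "NEXAFS difference map")
  } else warning("difference map missing from report")

  if (!is.null(run$traces)) {
    tr <- data.table::rbindlist(run$traces, idcol = "roi")
    fitcurves <- NULL
    if (!is.null(run$fit) && run$fit$convergence) {
      md <- .par_to_model(stats::setNames(run$fit$coef$value,
                                          run$fit$coef$name))
      tt <- seq(min(tr$delay_fs), max(tr$delay_fs), length.out = 600)
      fitcurves <- rbind(
        data.frame(roi = "excited", delay_fs = tt,
                   model = roi_signal(md$params, tt, "excited_526",
                                      md$a_excited)),
        data.frame(roi = "bleach", delay_fs = tt,
                   model = roi_signal(md$params, tt, "bleach_pi",
                                      md$a_bleach)))
    }
    plots$traces <-
      ggplot2::ggplot(tr, ggplot2::aes(x = delay_fs / 1000, y = signal)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = signal - se,
                                          ymax = signal + se),
                             width = 0, color = "grey55") +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::facet_wrap(~roi, ncol = 1, scales = "free_y") +
      ggplot2::labs(x = "pump-probe delay (ps)",
                    y = "integrated difference signal",
                    title = "ROI time traces (error bars: standard error of mean)")
    if (!is.null(fitcurves))
      plots$traces <- plots$traces +
        ggplot2::geom_line(data = fitcurves,
                           ggplot2::aes(y = model), color = "red3")
  }

  spcfg <- .cfg_spectral(run$config)
  params <- .cfg_kinetics(run$config)
  grid <- energy_grid(min(run$config$experiment$photon_energies),
                      max(run$config$experiment$photon_energies), 0.05)
  spectra <- default_spectra(grid = grid, config = spcfg)
  pop2ps <- model_populations(params, 2000)
  mixed <- mix_spectra(c(pipi = pop2ps$pipi,
                         npi = pop2ps$npi1 + pop2ps$npi2),
                       f_exc = params$f_exc, spectra,
                       dark = pop2ps$final * (1 - params$phi_recovery))
  ov <- rbind(data.frame(energy = grid, intensity = spectra$GS$intensity,
                         which = "ground state"),
              data.frame(energy = grid, intensity = mixed$intensity,
                         which = "2 ps after UV"))
  plots$spectra_overlay <-
    ggplot2::ggplot(ov, ggplot2::aes(energy, intensity, color = which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "photon energy (eV)", y = "relative absorption",
                  color = NULL, title = "Model spectra with and without UV")

  states <- c("GS", "pipi_FC", "pipi_saddle", "npi_min")
  sim <- data.table::rbindlist(lapply(states, function(st) {
    sp <- state_spectrum(st, grid = grid, config = spcfg,
                         include_edge = FALSE)
    scl <- if (st == "GS") 1 else params$f_exc
    data.frame(energy = grid, intensity = scl * sp$intensity, state = st)
  }))
  plots$state_spectra <-
    ggplot2::ggplot(sim, ggplot2::aes(energy, intensity, color = state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "photon energy (eV)", y = "relative absorption",
                  title = sprintf(
                    "Per-state spectra (excited states scaled by f_exc = %.2g)",
                    params$f_exc))

  for (nm in names(plots))
    suppressMessages(ggplot2::ggsave(
      file.path(out_dir, paste0("report_", nm, ".pdf")),
      plots[[nm]], width = 7, height = 5))
  invisible(plots)
}
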