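# Workflow commands: simulate / track / prc as single calls that read a
# config, run the pipeline, and write tables, plots and provenance metadata.
# The exec/crhr script is a thin command-line wrapper over these.

run_metadata <- function(config, seed) {
  list(package = "crhr",
       version = as.character(packageVersion("crhr")),
       seed = seed,
       config = config,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

write_metadata <- function(meta, dir) {
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
}

#' Simulate a recording to files
#'
#' Runs the simulator and writes `streams.csv` (generic dialect),
#' `ledger.csv` (ground truth) and `run_metadata.json` to `out_dir`.
#'
#' @param out_dir output directory.
#' @param n_days days to simulate (`>= 2`).
#' @param seed integer seed.
#' @param ... further arguments to [sim_config].
#' @return invisibly, the output directory.
#' @export
cmd_simulate <- function(out_dir, n_days = 14, seed = 1, ...) {
  cfg <- sim_config(n_days = n_days, seed = seed, ...)
  sim <- crhr_simulate(cfg)
  write_generic_csv(sim, out_dir)
  write_metadata(run_metadata(list(n_days = n_days), seed), out_dir)
  invisible(out_dir)
}

#' Track phases from device files
#'
#' Reads a device export, preprocesses it, tracks phases across all fit
#' windows, and writes `phase_track.csv`, `windows.csv`, an actogram PNG
#' with the phase overlay, and run metadata.
#'
#' @param paths input files.
#' @param out_dir output directory.
#' @param dialect input dialect (see [read_device_export]).
#' @param n_total_samples MCMC budget per window.
#' @param n_walkers ensemble size.
#' @param seed integer seed.
#' @param min_obs window observation floor.
#' @return invisibly, the `crhr_track`.
#' @export
cmd_track <- function(paths, out_dir, dialect = "generic",
                      n_total_samples = 100000, n_walkers = 32, seed = 1,
                      min_obs = 48) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_device_export(paths, dialect)
  prep <- crhr_preprocess(records, min_obs = min_obs)
  if (length(prep$windows) == 0)
    stop("no valid fit windows in the input")
  track <- track_phases(prep$windows, n_total_samples = n_total_samples,
                        n_walkers = n_walkers, seed = seed)
  write_phase_track(track, file.path(out_dir, "phase_track.csv"))
  write.csv(windows_manifest(prep$windows), file.path(out_dir, "windows.csv"),
            row.names = FALSE)
  png(file.path(out_dir, "actogram.png"), width = 900, height = 200 +
        40 * length(unique(format(prep$binned$bin_start, "%Y-%m-%d"))))
  plot_actogram(prep$binned, track)
  dev.off()
  write_metadata(run_metadata(list(dialect = dialect,
                                   n_total_samples = n_total_samples,
                                   n_walkers = n_walkers,
                                   min_obs = min_obs), seed), out_dir)
  invisible(track)
}

#' Estimate the PRC from device files
#'
#' Runs the full pipeline (preprocess, track, PRC) and writes `prc.csv`,
#' `prc_curve.json`, a PRC plot, optional shuffled-control and
#' non-overlapping (48-h) variants, and run metadata.
#'
#' @param paths input files.
#' @param out_dir output directory.
#' @param dialect input dialect.
#' @param n_total_samples MCMC budget per window.
#' @param seed integer seed.
#' @param shuffle also write a shuffled-activity control curve.
#' @param nonoverlap also write the 48-h non-overlapping variant.
#' @param track optionally, a precomputed `crhr_track` (with its `binned`
#'   series as attribute or supplied via `binned`).
#' @param binned precomputed `crhr_binned` series matching `track`.
#' @return invisibly, the `crhr_prc`.
#' @export
cmd_prc <- function(paths = NULL, out_dir, dialect = "generic",
                    n_total_samples = 100000, seed = 1, shuffle = FALSE,
                    nonoverlap = FALSE, track = NULL, binned = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(track) || is.null(binned)) {
    records <- read_device_export(paths, dialect)
    prep <- crhr_preprocess(records)
    usable <- length(prep$windows)
    if (usable < 2) stop("PRC needs at least 2 usable nights")
    track <- track_phases(prep$windows, n_total_samples = n_total_samples,
                          seed = seed)
    binned <- prep$binned
  }
  prc <- crhr_prc(track, binned, seed = seed)
  write_prc(prc, file.path(out_dir, "prc.csv"),
            file.path(out_dir, "prc_curve.json"))
  png(file.path(out_dir, "prc.png"), width = 800, height = 500)
  plot(prc)
  dev.off()
  if (shuffle) {
    ctrl <- crhr_prc(track, binned, shuffle = TRUE, seed = seed)
    write_prc(ctrl, file.path(out_dir, "prc_shuffled.csv"),
              file.path(out_dir, "prc_shuffled_curve.json"))
  }
  if (nonoverlap) {
    no <- prc_robustness_nonoverlap(track, binned, seed = seed)
    write_prc(no, file.path(out_dir, "prc_nonoverlap.csv"),
              file.path(out_dir, "prc_nonoverlap_curve.json"))
  }
  write_metadata(run_metadata(list(dialect = dialect,
                                   n_total_samples = n_total_samples,
                                   shuffle = shuffle,
                                   nonoverlap = nonoverlap), seed), out_dir)
  invisible(prc)
}

#' Actogram with phase overlay
#'
#' Raster plot of activity: one row per civil day (midnight to midnight,
#' optionally double-plotted to 48 h), activity as black bars, estimated
#' phase as a red line with a shaded 80% band.
#'
#' @param binned a `crhr_binned` series.
#' @param track optional `crhr_track` to overlay.
#' @param double_plot draw 48-h rows (default `TRUE`).
#' @param main plot title.
#' @export
plot_actogram <- function(binned, track = NULL, double_plot = TRUE,
                          main = "Actogram") {
  dates <- sort(unique(format(binned$bin_start, "%Y-%m-%d")))
  n <- length(dates)
  width_h <- if (double_plot) 48 else 24
  plot.new()
  plot.window(xlim = c(0, width_h), ylim = c(n + 0.5, 0.5))
  title(main = main, xlab = "hour of day")
  axis(1, at = seq(0, width_h, by = 6), labels = seq(0, width_h, by = 6) %% 24)
  axis(2, at = seq_len(n), labels = dates, las = 1, cex.axis = 0.6)

  hod <- clock_hours(binned$bin_start)
  day_str <- format(binned$bin_start, "%Y-%m-%d")
  smax <- max(binned$steps_per_min, 1, na.rm = TRUE)
  for (i in seq_len(n)) {
    rows <- list(c(i, 0))
    if (double_plot && i > 1) rows <- c(rows, list(c(i - 1, 24)))
    sel <- which(day_str == dates[i] & binned$steps_per_min > 0)
    for (r in rows) {
      hgt <- 0.8 * pmin(binned$steps_per_min[sel] / smax, 1)
      rect(hod[sel] + r[2], r[1] + 0.4, hod[sel] + r[2] + 1 / 12,
           r[1] + 0.4 - hgt, col = "black", border = NA)
    }
  }
  if (!is.null(track) && nrow(track)) {
    day_idx <- match(format(track$sleep_midpoint, "%Y-%m-%d"), dates)
    okr <- !is.na(day_idx) & !is.na(track$phase_mean_h)
    ph <- track$phase_mean_h[okr]; yi <- day_idx[okr]
    lo <- ph - wrap_hours(ph - track$ci80_lo[okr])
    hi <- ph + wrap_hours(track$ci80_hi[okr] - ph)
    polygon(c(lo, rev(hi)), c(yi, rev(yi)), col = rgb(1, 0, 0, 0.2),
            border = NA)
    lines(ph, yi, col = "red", lwd = 2)
    points(ph, yi, col = "red", pch = 16, cex = 0.6)
  }
  invisible(NULL)
}
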