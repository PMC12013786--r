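#' Run a configured analysis stage
#'
#' Single entry point wiring the pipeline stages. A run configuration is a
#' list (or a YAML file) with at least `subcommand` and `out` (output
#' directory); stage parameters default to the package defaults documented
#' on each function. Every stochastic stage receives an explicit seed
#' (default 1). Alongside its outputs each run writes `run_manifest.json`
#' echoing the configuration, the seeds, the package version and MD5
#' checksums of the inputs, so any result can be regenerated exactly.
#'
#' Subcommands:
#' * `fixtures`: write the seeded fixture set ([write_fixtures()]).
#' * `dims`: latent-dimensionality report for a spike CSV
#'   ([select_dimensionality()]); writes `report.json`.
#' * `flex`: displacement/dispersion for all pairs ([flex_pairwise()]);
#'   writes `flex.csv`.
#' * `simulate`: one simulation scenario ([run_scenario()]); writes
#'   `rasters.csv` and `report.json`.
#' * `muap`: locate units from an EMG matrix CSV plus spike CSV
#'   ([spike_triggered_average()], [locate_unit()]); writes `locations.csv`
#'   and `distances.csv`.
#'
#' @param config A named list, or path to a YAML file. Recognized fields per
#'   subcommand are documented above; unknown fields are an error.
#' @return Invisibly, the manifest list. Stage errors propagate.
#' @export
run_workbench <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$subcommand)) {
    abort("Config must be a list (or YAML file) with a `subcommand` field.")
  }
  known <- c("subcommand", "out", "seed", "input", "torque", "segments",
             "kmax", "fs", "fs_out", "kernel_dur", "max_pause", "max_lag",
             "norm_tol", "scenario", "duration", "dt", "n_per_pool", "emg",
             "layout", "window")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    abort(paste0("Unknown config field(s): ", paste(extra, collapse = ", ")))
  }
  out_dir <- config$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  sub <- config$subcommand
  inputs <- character(0)
  artifacts <- switch(
    sub,
    fixtures = {
      write_fixtures(out_dir)
      "manifest.json"
    },
    dims = {
      inputs <- config$input
      spikes <- read_spike_csv(config$input)
      segs <- parse_segments(config$segments)
      dur <- max(spikes$time_s, if (!is.null(segs)) segs$end)
      pop <- population_recording(spikes, duration = dur,
                                  fs = config$fs %||% 2048, segments = segs)
      rep <- select_dimensionality(pop, kmax = config$kmax %||% 10,
                                   kernel_dur = config$kernel_dur %||% 0.4,
                                   fs_out = config$fs_out,
                                   max_pause = config$max_pause %||% 0.4,
                                   seed = seed)
      jsonlite::write_json(
        rep[c("r2_data", "r2_surrogate", "k_slope", "k_5pct", "k_mse",
              "surrogate_slope", "n_units", "kmax")],
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE, null = "null")
      "report.json"
    },
    flex = {
      inputs <- config$input
      spikes <- read_spike_csv(config$input)
      pop <- population_recording(spikes, fs = config$fs %||% 2048)
      rm <- smooth_rates(pop, fs_out = config$fs_out)
      tab <- flex_pairwise(rm, max_lag = config$max_lag %||% 0.025,
                           norm_tol = config$norm_tol)
      utils::write.csv(as.data.frame(tab), file.path(out_dir, "flex.csv"),
                       row.names = FALSE, quote = FALSE, eol = "\n")
      "flex.csv"
    },
    simulate = {
      run <- run_scenario(config$scenario %||% "i", seed = seed,
                          duration = config$duration %||% 60,
                          dt = config$dt %||% 5e-5,
                          n_per_pool = config$n_per_pool %||% 300,
                          kmax = config$kmax %||% 10,
                          fs_out = config$fs_out %||% 64)
      write_spike_csv(run$pop$spikes, file.path(out_dir, "rasters.csv"))
      rep <- run$report
      jsonlite::write_json(
        c(list(scenario = run$scenario, n_active = run$n_active,
               mean_rate_mn = run$mean_rate_mn,
               mean_rate_rc = run$mean_rate_rc,
               baseline_e = run$baseline_e),
          rep[c("r2_data", "r2_surrogate", "k_slope", "k_5pct", "k_mse")]),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE, null = "null")
      c("rasters.csv", "report.json")
    },
    muap = {
      inputs <- c(config$emg, config$input)
      emg <- t(as.matrix(utils::read.csv(config$emg)))
      spikes <- read_spike_csv(config$input)
      fs <- config$fs %||% 2048
      layout <- do.call(grid_layout, config$layout %||% list())
      pop <- population_recording(spikes, fs = fs,
                                  duration = ncol(emg) / fs)
      locs <- purrr::map_dfr(unit_ids(pop), function(u) {
        tpl <- spike_triggered_average(emg, spike_times(pop, u), fs,
                                       window = config$window %||% 0.05)
        loc <- locate_unit(list(amplitude_map(tpl, layout)),
                           grid_layout(layout$rows, layout$cols,
                                       layout$inter_electrode_mm, 1,
                                       layout$inter_grid_mm))
        dplyr::mutate(loc, unit_id = u, .before = 1)
      })
      utils::write.csv(as.data.frame(locs),
                       file.path(out_dir, "locations.csv"),
                       row.names = FALSE, quote = FALSE, eol = "\n")
      idx <- utils::combn(seq_len(nrow(locs)), 2)
      dists <- tibble(
        unit_a = locs$unit_id[idx[1, ]], unit_b = locs$unit_id[idx[2, ]],
        distance_mm = sqrt((locs$x_mm[idx[1, ]] - locs$x_mm[idx[2, ]])^2 +
                             (locs$y_mm[idx[1, ]] - locs$y_mm[idx[2, ]])^2))
      utils::write.csv(as.data.frame(dists),
                       file.path(out_dir, "distances.csv"),
                       row.names = FALSE, quote = FALSE, eol = "\n")
      c("locations.csv", "distances.csv")
    },
    abort(sprintf("Unknown subcommand '%s'.", sub))
  )
  manifest <- list(
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("muflex")),
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL,
    artifacts = artifacts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

parse_segments <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    parts <- strsplit(strsplit(x, ",")[[1]], "-")
    return(tibble(start = as.numeric(vapply(parts, `[`, "", 1)),
                  end = as.numeric(vapply(parts, `[`, "", 2))))
  }
  as_tibble(x)
}
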