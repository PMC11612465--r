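#' Printed study tables
#'
#' Small reference tables shipped with the package: the frame-37 tracked
#' table of Tube A (`"frame37"`), Tube A's per-frame region statistics
#' (`"tubeA_stats"`), the six-tube summary table (`"summaries"`), and the
#' per-tube extracted-frame counts (`"frame_counts"`).
#'
#' @param name which table to load.
#' @return A data.frame.
#' @export
study_table <- function(name = c("frame37", "tubeA_stats", "summaries",
                                 "frame_counts")) {
  name <- match.arg(name)
  file <- c(frame37 = "table_tubeA_frame37.csv",
            tubeA_stats = "table_tubeA_region_stats.csv",
            summaries = "table_tube_summaries.csv",
            frame_counts = "frame_counts.csv")[[name]]
  path <- system.file("extdata", file, package = "tubeswarm", mustWork = TRUE)
  utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
}

resolve_geometry <- function(g) {
  if (inherits(g, "tube_geometry")) return(g)
  if (is.character(g)) return(read_tube_config(g))
  if (is.list(g)) {
    if (!is.null(g$path)) return(read_tube_config(g$path))
    if (!is.null(g$angle)) {
      args <- list(included_angle_deg = g$angle)
      for (f in c("opening_width", "length", "tube_id"))
        if (!is.null(g[[f]])) args[[f]] <- g[[f]]
      return(do.call(make_tube_fixture, args))
    }
    if (!is.null(g$wall_left))
      return(tube_geometry(do.call(rbind, g$wall_left),
                           do.call(rbind, g$wall_right),
                           tube_id = g$tube_id %||% "tube"))
  }
  stop("cannot interpret geometry specification")
}

as_table <- function(x, validate = NULL) {
  df <- if (is.character(x)) utils::read.csv(x, check.names = TRUE) else x
  if (!is.null(validate)) df <- validate(df)
  df
}

#' Run the full region-statistics and law-fitting analysis
#'
#' For each configured tube: load (or take) its frame tables or precomputed
#' per-frame statistics, flag and drop anomalous rows, compute the per-frame
#' region statistics, and average the ratios over the tube's frame window.
#' With two or more tubes, fits the linear speed-ratio and exponential
#' count-ratio laws against the cosine of the included angle. Kernel density
#' occupancy curves are computed for tubes with raw frames.
#'
#' @param config a list (or YAML file path) with a `tubes` list — each entry
#'   having `tube_id`, `geometry` (a `tube_geometry`, a config path, or a
#'   list with `angle`), one of `frames` (tracked CSV path or data.frame) or
#'   `stats` (per-frame statistics path or data.frame), and an optional
#'   `window` of frame numbers — plus optional `mse_scale` and `out_dir`.
#' @param out_dir optional output directory (overrides the config's);
#'   per-tube statistics CSVs, the summary CSV, fitted-law JSON and density
#'   CSVs are written there.
#' @return List: `stats` (named per-tube data.frames), `summaries`
#'   (one row per tube), `linear_law`, `exponential_law` (NULL with < 2
#'   tubes), `densities` (named list of `density_curve`s).
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$tubes) || length(config$tubes) == 0)
    stop("analysis config must list at least one tube")
  out_dir <- out_dir %||% config$out_dir
  mse_scale <- config$mse_scale %||% "linear"

  stats_by_tube <- list()
  densities <- list()
  summaries <- NULL
  for (tube in config$tubes) {
    geom <- resolve_geometry(tube$geometry)
    id <- tube$tube_id %||% geom$tube_id
    geom$tube_id <- id
    if (!is.null(tube$frames)) {
      tab <- as_table(tube$frames, validate_frame_table)
      if (nrow(tab) == 0) stop("tube ", id, ": empty frames input")
      tab <- clean_frame_table(tab)
      st <- region_stats(tab, geom)
      inside <- classify_points(tab$x, tab$y, geom) != "outside"
      if (sum(inside) >= 2) {
        densities[[paste0(id, "_x")]] <- kde_1d(tab$x[inside], axis = "x")
        densities[[paste0(id, "_y")]] <- kde_1d(tab$y[inside], axis = "y")
      }
    } else if (!is.null(tube$stats)) {
      st <- as_table(tube$stats)
      need <- c("frame", "ratio_s", "ratio_n")
      if (!all(need %in% names(st)))
        stop("tube ", id, ": stats input lacks columns ",
             paste(setdiff(need, names(st)), collapse = ", "))
    } else stop("tube ", id, ": provide either frames or stats")
    stats_by_tube[[id]] <- st
    window <- if (!is.null(tube$window)) as.numeric(tube$window) else NULL
    summaries <- rbind(summaries, summarize_tube(st, geom, frames = window))
  }

  linear_law <- exponential_law <- NULL
  if (nrow(summaries) >= 2) {
    linear_law <- fit_linear_law(summaries$cosine, summaries$mean_ratio_s)
    exponential_law <- fit_exponential_law(summaries$cosine,
                                           summaries$mean_ratio_n,
                                           mse_scale = mse_scale)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(stats_by_tube))
      utils::write.csv(stats_by_tube[[id]],
                       file.path(out_dir, paste0("region_stats_", id, ".csv")),
                       row.names = FALSE, quote = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "tube_summaries.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(linear_law)) {
      fits <- list(
        speed_ratio_law = jsonlite::fromJSON(law_to_json(linear_law)),
        count_ratio_law = jsonlite::fromJSON(law_to_json(exponential_law)))
      jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    for (nm in names(densities))
      utils::write.csv(as.data.frame(densities[[nm]]),
                       file.path(out_dir, paste0("density_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
  }
  list(stats = stats_by_tube, summaries = summaries,
       linear_law = linear_law, exponential_law = exponential_law,
       densities = densities)
}

#' Run a swarm simulation from a config
#'
#' @param config list (or YAML path) with `geometry` (as in
#'   [run_analysis()]), optional `params` (arguments to [model_params()]),
#'   and `n_steps`.
#' @param seed RNG seed.
#' @param out optional CSV path for the simulated frame tables.
#' @return The `swarm_simulation`, invisibly when `out` is given.
#' @export
run_simulation <- function(config, seed = 1, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  geom <- resolve_geometry(config$geometry)
  params <- do.call(model_params, config$params %||% list())
  sim <- simulate_swarm(params, geom, n_steps = config$n_steps %||% 500,
                        seed = seed)
  if (!is.null(out)) {
    write_frame_tables(sim$frames, out)
    return(invisible(sim))
  }
  sim
}

#' Generate synthetic frames from a config
#'
#' @param config list (or YAML path) mirroring [synthetic_spec()] fields,
#'   with `geometry` as in [run_analysis()].
#' @param seed overrides the config's seed when non-NULL.
#' @param out optional CSV path.
#' @return The generated `frame_table`, invisibly when `out` is given.
#' @export
run_synth <- function(config, seed = NULL, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  geom <- resolve_geometry(config$geometry)
  args <- config[setdiff(names(config), c("geometry", "out"))]
  if (!is.null(seed)) args$seed <- seed
  spec <- do.call(synthetic_spec, c(list(geometry = geom), args))
  frames <- generate_frames(spec)
  if (!is.null(out)) {
    write_frame_tables(frames, out)
    return(invisible(frames))
  }
  frames
}

#' Validate a tracked frame-table CSV
#'
#' Reads the CSV, reports anomalous rows, and returns the flags.
#'
#' @param path CSV path.
#' @param ... passed to [flag_anomalies()].
#' @return data.frame of flags (invisibly); flagged rows are printed.
#' @export
run_validate <- function(path, ...) {
  tab <- read_frame_tables(path)
  flags <- flag_anomalies(tab, ...)
  if (nrow(flags) == 0) {
    message("no anomalous rows in ", path)
  } else {
    message(nrow(flags), " anomalous row(s) in ", path, ":")
    for (i in seq_len(nrow(flags)))
      message(sprintf("  frame %s fish %s: %s", flags$frame[i],
                      flags$number[i], flags$reason[i]))
  }
  invisible(flags)
}

#' Frame-table bookkeeping report
#'
#' Totals the number of extracted frame tables across tubes. With the
#' study's extraction schedule (18 frames in tube A, 10 in each of B, C, E
#' and G, 7 in each of D, F and H) the total is 79.
#'
#' @param frame_counts named numeric vector or data.frame with columns
#'   `tube`, `n_frames`; defaults to the study's schedule.
#' @return list with `per_tube` (data.frame) and `total`.
#' @export
run_report <- function(frame_counts = NULL) {
  if (is.null(frame_counts)) frame_counts <- study_table("frame_counts")
  if (is.data.frame(frame_counts)) {
    per_tube <- data.frame(tube = as.character(frame_counts$tube),
                           n_frames = as.numeric(frame_counts$n_frames))
  } else {
    per_tube <- data.frame(tube = names(frame_counts),
                           n_frames = as.numeric(frame_counts))
  }
  list(per_tube = per_tube, total = sum(per_tube$n_frames))
}
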