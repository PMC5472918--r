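#' Default pipeline configuration
#'
#' @param seed Master seed for simulation and SOM training.
#' @param duration Track duration in seconds per session.
#' @param n_individuals Individuals per group.
#' @param groups Preset names to simulate (default: all nine).
#' @param trajectory_file Optional path of an existing trajectory table;
#'   when set, ingestion replaces simulation.
#' @param run_som Run the SOM/ethogram stage (default TRUE).
#' @param fractal_window Fractal window length in seconds.
#' @param slip_threshold Slip detector threshold, mm per sub-segment.
#' @param write_tracks Also write the simulated trajectory table.
#' @param make_figures Write PNG figures (component planes, dendrogram,
#'   pattern fractions).
#' @return Named list of settings understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1, duration = 1800, n_individuals = 15,
                            groups = NULL, trajectory_file = NULL,
                            run_som = TRUE, fractal_window = 1800,
                            slip_threshold = 2, write_tracks = FALSE,
                            make_figures = FALSE) {
  list(seed = seed, duration = duration, n_individuals = n_individuals,
       groups = groups, trajectory_file = trajectory_file,
       run_som = run_som, fractal_window = fractal_window,
       slip_threshold = slip_threshold, write_tracks = write_tracks,
       make_figures = make_figures)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return A configuration list (see [pipeline_config()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(pipeline_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Executes simulate (or ingest) -> extract -> fractal -> occupancy ->
#' SOM train -> classify -> summarize, writes every stage table to
#' `out_dir` as CSV (plus the SOM model as JSON and a run log with the
#' seed and settings), and returns the bundle. Fully reproducible from the
#' configuration and seed; any stage error aborts with the stage name.
#'
#' @param config Configuration list from [pipeline_config()] or
#'   [read_config()] (or a YAML path).
#' @param out_dir Output directory (default: no files are written).
#' @return Invisibly, a list with `tracks`, `features`, `dimensions`,
#'   `occupancy`, `model`, `clusters`, `ethogram`, `summary`,
#'   `correlations`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(pipeline_config(), config)
  a <- arena()

  tracks <- stage("simulate/ingest", {
    if (!is.null(config$trajectory_file)) {
      read_tracks(config$trajectory_file, arena = a)
    } else {
      presets <- default_presets()
      if (!is.null(config$groups)) {
        missing <- setdiff(config$groups, names(presets))
        if (length(missing)) {
          stop(sprintf("no preset for group(s): %s",
                       paste(missing, collapse = ", ")))
        }
        presets <- presets[config$groups]
      }
      cfg <- simulation_config(arena = a, duration = config$duration,
                               n_individuals = config$n_individuals,
                               seed = config$seed)
      generate_study(cfg, presets)
    }
  })

  features <- stage("extract", {
    extract_features(tracks, slip_threshold = config$slip_threshold)
  })
  dimensions <- stage("fractal", {
    track_dimensions(tracks, window = config$fractal_window)
  })
  occupancy <- stage("occupancy", occupancy_table(tracks))

  model <- clusters <- ethogram <- NULL
  if (isTRUE(config$run_som)) {
    model <- stage("som-train", {
      train_som(normalize_features(features), seed = config$seed)
    })
    clusters <- stage("cluster", {
      label_patterns(model, cluster_codebook(model, k = 9))
    })
    ethogram <- stage("classify", classify_segments(features, model, clusters))
  }

  summary_tab <- stage("summarize", {
    summarize_groups(features, dimensions, occupancy)
  })
  correlations <- stage("correlate", correlation_matrix(features, dimensions))

  bundle <- list(tracks = tracks, features = features,
                 dimensions = dimensions, occupancy = occupancy,
                 model = model, clusters = clusters, ethogram = ethogram,
                 summary = summary_tab, correlations = correlations)

  if (!is.null(out_dir)) {
    stage("report", write_bundle(bundle, config, out_dir))
  }
  invisible(bundle)
}

write_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  if (isTRUE(config$write_tracks)) {
    write_tracks(bundle$tracks, file.path(out_dir, "tracks.csv"))
  }
  wcsv(bundle$features, "features.csv")
  wcsv(bundle$dimensions, "dimensions.csv")
  wcsv(bundle$occupancy, "occupancy.csv")
  wcsv(bundle$summary, "group_summary.csv")
  corr <- as.data.frame(bundle$correlations)
  corr <- cbind(parameter = rownames(corr), corr)
  wcsv(corr, "correlations.csv")
  if (!is.null(bundle$model)) {
    write_som_model(bundle$model, file.path(out_dir, "som_model.json"))
    wcsv(bundle$ethogram$segments, "ethogram_segments.csv")
    wcsv(bundle$ethogram$group_fractions, "pattern_fractions.csv")
    if (isTRUE(config$make_figures)) {
      grDevices::png(file.path(out_dir, "component_planes.png"),
                     width = 900, height = 600)
      plot_component_planes(bundle$model)
      grDevices::dev.off()
      grDevices::png(file.path(out_dir, "dendrogram.png"),
                     width = 900, height = 600)
      plot_codebook_dendrogram(bundle$clusters)
      grDevices::dev.off()
      grDevices::png(file.path(out_dir, "pattern_fractions.png"),
                     width = 900, height = 600)
      plot_pattern_fractions(bundle$ethogram)
      grDevices::dev.off()
    }
  }
  log_lines <- c(
    sprintf("ethoscreen run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", config$seed),
    sprintf("duration: %g s, n_individuals: %d",
            config$duration, as.integer(config$n_individuals)),
    sprintf("groups: %s",
            if (is.null(config$groups)) "all" else
              paste(config$groups, collapse = ", ")),
    sprintf("slip_threshold: %g mm, fractal_window: %g s",
            config$slip_threshold, config$fractal_window),
    sprintf("tracks: %d, segments: %d",
            length(bundle$tracks), nrow(bundle$features)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
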