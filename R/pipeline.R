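#' Pipeline configuration
#'
#' Collects every parameter of the full analysis. Input is either
#' `simulate` (a [gait_sim_config()]) or the three file paths; the
#' remaining fields control the processing stages.
#'
#' @param fsr_file,kinematics_file,layout_file Input file paths (file
#'   mode). `layout_file = NULL` uses the bundled handle layout.
#' @param simulate A [gait_sim_config()] to generate the inputs instead of
#'   reading files.
#' @param segmentation A [segmentation_config()].
#' @param sync_max_lag_s Half-width of the synchronization shift search.
#' @param sg_window Savitzky-Golay window length (samples, odd).
#' @param n_central_strides Number of central strides analyzed.
#' @param min_strides Stride-consistency threshold for retaining an event.
#' @param prominence_frac Extremum prominence floor (fraction of channel
#'   IQR).
#' @param exclude_phases Phase labels not used as event references.
#' @param out_dir Output directory for the run report; `NULL` writes
#'   nothing.
#' @param seed Seed applied before simulation (ignored in file mode).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fsr_file = NULL, kinematics_file = NULL,
                            layout_file = NULL, simulate = NULL,
                            segmentation = segmentation_config(),
                            sync_max_lag_s = 5, sg_window = 11L,
                            n_central_strides = 30L, min_strides = 25L,
                            prominence_frac = 0.05,
                            exclude_phases = "terminal_stance",
                            out_dir = NULL, seed = 1L) {
  if (is.null(simulate)) {
    for (f in c(fsr_file, kinematics_file, layout_file)) {
      if (!is.null(f) && !file.exists(f)) {
        stop("input file not found: ", f, call. = FALSE)
      }
    }
    if (is.null(fsr_file) || is.null(kinematics_file)) {
      stop("either 'simulate' or both input files must be given",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      fsr_file = fsr_file, kinematics_file = kinematics_file,
      layout_file = layout_file, simulate = simulate,
      segmentation = segmentation, sync_max_lag_s = sync_max_lag_s,
      sg_window = as.integer(sg_window),
      n_central_strides = as.integer(n_central_strides),
      min_strides = as.integer(min_strides),
      prominence_frac = prominence_frac,
      exclude_phases = exclude_phases, out_dir = out_dir,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full gait-event pipeline
#'
#' Executes the processing chain in acquisition-to-result order:
#' synchronize the cane and reference streams on their cane-inclination
#' signals; segment the reference kinematics into gait phases; compute the
#' grip-pressure variables; smooth them with the 3rd-order Savitzky-Golay
#' filter and differentiate; restrict to the central strides; detect
#' per-stride extrema; and consolidate them into stride-consistent gait
#' events referenced to phase onsets.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a `gait_run_report` list: `sync` (the
#'   [synchronize()] result), `timeline` (segmented phases),
#'   `central_timeline`, `events` (the consolidated [consolidate_events()]
#'   table), `candidates`, `normalized` (stride-normalized curves),
#'   `derived` (the smoothed derived series, reference clock) and
#'   `params` (every parameter used). When `cfg$out_dir` is set, writes
#'   `report.json`, `events.tsv` and `timeline.tsv` there.
#' @export
run_pipeline <- function(cfg = pipeline_config(simulate = gait_sim_config())) {
  stopifnot(inherits(cfg, "pipeline_config"))
  inputs <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim_cfg <- cfg$simulate
      sim_cfg$seed <- cfg$seed
      sim <- simulate_gait(sim_cfg)
      list(
        fsr = sim$fsr, kin = sim$kin, layout = default_handle_layout(),
        truth = sim$truth
      )
    } else {
      list(
        fsr = read_fsr_series(cfg$fsr_file),
        kin = read_kinematics_series(cfg$kinematics_file),
        layout = if (is.null(cfg$layout_file)) {
          default_handle_layout()
        } else {
          read_handle_layout(cfg$layout_file)
        },
        truth = NULL
      )
    }
  })
  if (is.null(inputs$fsr$cane_angle_deg)) {
    stop("stage 'sync': FSR stream carries no cane inclination signal",
      call. = FALSE
    )
  }
  sync <- stage("sync", synchronize(
    list(time_s = inputs$fsr$time_s, angle_deg = inputs$fsr$cane_angle_deg),
    list(time_s = inputs$kin$time_s, angle_deg = inputs$kin$cane_angle_deg),
    max_lag_s = cfg$sync_max_lag_s
  ))
  fsr <- inputs$fsr
  fsr$time_s <- fsr$time_s + sync$lag # cane stream now on the reference clock

  timeline <- stage("segment", segment_gait(inputs$kin, cfg$segmentation))
  derived <- stage("variables", {
    d <- compute_derived(fsr, inputs$layout)
    d <- smooth_derived(d, cfg$sg_window)
    differentiate(d)
  })
  central <- stage(
    "central_strides",
    select_central_strides(timeline, cfg$n_central_strides)
  )
  cands <- stage("extrema", detect_stride_extrema(
    derived, central,
    prominence_frac = cfg$prominence_frac,
    exclude_phases = cfg$exclude_phases
  ))
  events <- stage("events", consolidate_events(
    cands,
    min_strides = cfg$min_strides,
    total_strides = cfg$n_central_strides
  ))
  normalized <- stage("normalize", normalize_stride_time(derived, central))

  report <- structure(
    list(
      sync = sync, timeline = timeline, central_timeline = central,
      events = events, candidates = cands, normalized = normalized,
      derived = derived, truth = inputs$truth,
      params = cfg[setdiff(names(cfg), "simulate")]
    ),
    class = "gait_run_report"
  )
  if (!is.null(cfg$out_dir)) {
    stage("output", write_run_report(report, cfg$out_dir))
  }
  invisible(report)
}

#' Write a run report to disk
#'
#' Emits `report.json` (synchronization result, parameters, consolidated
#' events), `events.tsv` and `timeline.tsv` into `dir`.
#'
#' @param report A `gait_run_report` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- as.data.frame(report$events)
  ev$offsets <- NULL
  json <- list(
    sync = list(
      lag_s = report$sync$lag,
      peak_correlation = report$sync$peak_correlation,
      resampled_length = report$sync$resampled_length
    ),
    n_strides_segmented = nrow(report$timeline),
    n_strides_analyzed = nrow(report$central_timeline),
    events = ev,
    params = Filter(
      function(x) is.numeric(x) || is.character(x) || is.logical(x),
      c(report$params, unclass(report$params$segmentation))
    )
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_event_table(report$events, file.path(dir, "events.tsv"))
  utils::write.table(as.data.frame(report$central_timeline),
    file.path(dir, "timeline.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}

#' @export
print.gait_run_report <- function(x, ...) {
  cat("Gait event pipeline run\n")
  print(x$sync)
  cat(sprintf(
    "Strides: %d segmented, %d analyzed\n",
    nrow(x$timeline), nrow(x$central_timeline)
  ))
  print(x$events)
  invisible(x)
}
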