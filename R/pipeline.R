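#' Configuration of a synthetic observation season
#'
#' Defines a multi-day, multi-treatment observation campaign mirroring the
#' structure of a lighting-treatment study: three housed groups filmed once
#' in the morning and once in the afternoon each day, with a datalogger
#' recording the thermal environment throughout. The default ground truth
#' encodes the qualitative alternative the package is validated against:
#' motility (unrest ground truth) decreasing blue > green > red, and feeder
#' attraction (cluster ground truth) highest under red. Recording length and
#' day count default to a desk-scale season (6 days x 2 periods, 90-s
#' recordings at 1 fps); the structure, not the volume, of a full campaign.
#'
#' @param treatments Tibble with `name`, `step_sigma`, `attraction_beta`.
#' @param n_days Number of observation days.
#' @param duration_s Length of each recording in seconds.
#' @param fps Output frame rate (1 fps pairs frames 1 s apart).
#' @param morning_hour,afternoon_hour Recording start hours (local clock).
#' @param comfort_schedule Optional character vector, one class per
#'   day-period slot (length `2 * n_days`, order d1-morning, d1-afternoon,
#'   d2-morning, ...); defaults to comfort/heat/cold in proportions 49:20:15
#'   cycled deterministically over the slots.
#' @param start_date First day of the season.
#' @param flock Baseline [flock_sim_config()] whose arena/bird geometry all
#'   treatments share (its sigma/beta/seed fields are overridden per
#'   recording).
#' @return A `season_config` list.
#' @export
season_config <- function(treatments = tibble::tibble(
                            name = c("blue", "green", "red"),
                            step_sigma = c(10, 5, 2),
                            attraction_beta = c(0, 0, 0.4)),
                          n_days = 6, duration_s = 90, fps = 1,
                          morning_hour = 8, afternoon_hour = 16,
                          comfort_schedule = NULL,
                          start_date = as.Date("2020-06-10"),
                          flock = flock_sim_config(duration_s = duration_s,
                                                   fps_out = fps)) {
  if (!all(c("name", "step_sigma", "attraction_beta") %in% names(treatments)))
    stop_config("treatments needs columns name, step_sigma, attraction_beta")
  n_slots <- 2L * n_days
  if (is.null(comfort_schedule)) {
    pool <- c("comfort", "heat", "cold")
    counts <- round(n_slots * c(49, 20, 15) / 84)
    counts[1] <- n_slots - sum(counts[-1])
    comfort_schedule <- rep(pool, counts)[seq_len(n_slots)]
  }
  if (length(comfort_schedule) != n_slots)
    stop_config("comfort_schedule must have one class per day-period slot")
  structure(list(treatments = treatments, n_days = n_days,
                 duration_s = duration_s, fps = fps,
                 morning_hour = morning_hour, afternoon_hour = afternoon_hour,
                 comfort_schedule = comfort_schedule, start_date = start_date,
                 flock = flock), class = "season_config")
}

#' Simulate a full observation season to disk
#'
#' For every treatment x day x period, simulates a flock recording (with
#' per-recording seeds derived from `seed`), renders it to PNG frames, and
#' writes a recording manifest, the season's thermal log, and the generative
#' ground truth. The thermal schedule is shared by all treatments (one
#' climate); hours outside recording slots are thermoneutral.
#'
#' @param cfg A [season_config()].
#' @param out_dir Output directory.
#' @param seed Master seed for the whole season.
#' @return Invisibly, a list with `manifest`, `thermal`, `ground_truth`
#'   paths and the manifest tibble.
#' @export
simulate_season <- function(cfg, out_dir, seed = 1L) {
  stopifnot(inherits(cfg, "season_config"))
  dir.create(file.path(out_dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  slots <- tidyr::expand_grid(
    day = seq_len(cfg$n_days),
    period = c("morning", "afternoon")
  )
  slots$slot <- seq_len(nrow(slots))
  slots$comfort_scheduled <- cfg$comfort_schedule
  # hourly thermal schedule across the season, comfort outside recordings
  n_hours <- 24L * cfg$n_days
  schedule <- rep("comfort", n_hours)
  slot_hour <- (slots$day - 1) * 24 +
    ifelse(slots$period == "morning", cfg$morning_hour, cfg$afternoon_hour)
  schedule[slot_hour + 1] <- slots$comfort_scheduled
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  thermal <- simulate_thermal(n_hours, schedule, seed = seed, start = t0)
  rows <- list()
  rec_i <- 0L
  for (ti in seq_len(nrow(cfg$treatments))) {
    tr <- cfg$treatments[ti, ]
    for (si in seq_len(nrow(slots))) {
      rec_i <- rec_i + 1L
      rid <- sprintf("%s_d%02d_%s", tr$name, slots$day[si], slots$period[si])
      fc <- cfg$flock
      fc$step_sigma <- tr$step_sigma
      fc$attraction_beta <- tr$attraction_beta
      fc$seed <- as.integer((seed * 1000L + rec_i * 7L) %% .Machine$integer.max)
      traj <- simulate_flock(fc)
      masks <- render_frames(traj, fc)
      fdir <- file.path(out_dir, "frames", rid)
      write_frame_masks(masks, fdir)
      start_ts <- t0 + ((slots$day[si] - 1) * 24 +
                        ifelse(slots$period[si] == "morning",
                               cfg$morning_hour, cfg$afternoon_hour)) * 3600
      rows[[rec_i]] <- tibble::tibble(
        recording_id = rid, treatment = tr$name,
        date = as.character(cfg$start_date + slots$day[si] - 1),
        period = slots$period[si],
        start_ts = format(start_ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        duration_s = cfg$duration_s,
        frames_dir = file.path("frames", rid),
        n_frames = length(masks),
        step_sigma = tr$step_sigma, attraction_beta = tr$attraction_beta,
        comfort_scheduled = slots$comfort_scheduled[si]
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  mpath <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  tpath <- file.path(out_dir, "thermal.csv")
  write_thermal_csv(thermal, tpath)
  gpath <- file.path(out_dir, "ground_truth.csv")
  readr::write_csv(manifest[, c("recording_id", "treatment", "step_sigma",
                                "attraction_beta", "comfort_scheduled")], gpath)
  invisible(list(manifest = mpath, thermal = tpath, ground_truth = gpath,
                 recordings = manifest))
}

#' Pipeline run configuration
#'
#' Bundles everything one end-to-end analysis needs: the recording manifest
#' and thermal log written by [simulate_season()] (or assembled for real
#' footage), the camera geometry, segmentation settings, the cluster-index
#' variant, comfort thresholds and the seed. Paths are validated up front so
#' a misconfigured run is refused before any computation.
#'
#' @param data_dir Directory holding `manifest.csv`, `thermal.csv` and the
#'   frame directories.
#' @param out_dir Report output directory.
#' @param camera A [camera_geometry()].
#' @param sigma_px,method,threshold,polarity,min_area Segmentation settings,
#'   see [segment_frames()].
#' @param variant Cluster-index variant, see [cluster_index()].
#' @param thresholds A [comfort_thresholds()].
#' @param rule Comfort classification rule, see [classify_comfort()].
#' @param alpha Significance level of the comparison tables.
#' @param seed Seed echoed into the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(data_dir, out_dir,
                       camera = camera_geometry(),
                       sigma_px = 1, method = "otsu", threshold = NULL,
                       polarity = "bright_birds", min_area = 50,
                       variant = "n_minus_1",
                       thresholds = comfort_thresholds(), rule = "thi_only",
                       alpha = 0.05, seed = 1L) {
  for (f in c("manifest.csv", "thermal.csv"))
    if (!file.exists(file.path(data_dir, f)))
      stop_config(paste0("missing ", f, " in ", data_dir))
  if (!inherits(camera, "camera_geometry"))
    stop_config("camera must be a camera_geometry object (height, angle, sensor width)")
  structure(list(data_dir = data_dir, out_dir = out_dir, camera = camera,
                 sigma_px = sigma_px, method = method, threshold = threshold,
                 polarity = polarity, min_area = min_area, variant = variant,
                 thresholds = thresholds, rule = rule, alpha = alpha,
                 seed = as.integer(seed)), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level keys `data_dir`, `out_dir` and optionally `camera`
#' (`height_cm`, `alpha_deg`, `sensor_w_px`), `segmentation` (`sigma_px`,
#' `method`, `threshold`, `polarity`, `min_area`), `variant`, `thresholds`
#' (`thi_cold`, `thi_heat`, `t_cold`, `t_heat`), `rule`, `alpha`, `seed`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$data_dir) || is.null(y$out_dir))
    stop_config("run config must set data_dir and out_dir")
  cam <- do.call(camera_geometry, as.list(y$camera))
  thr <- do.call(comfort_thresholds, as.list(y$thresholds))
  seg <- if (is.null(y$segmentation)) list() else y$segmentation
  args <- c(list(data_dir = y$data_dir, out_dir = y$out_dir, camera = cam,
                 thresholds = thr), seg)
  for (f in c("variant", "rule", "alpha", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(run_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage [", name, "] failed: ", conditionMessage(e)),
          class = "hensight_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes segment -> index -> thermal labeling -> aggregation -> report on
#' a recording manifest. Every stage failure aborts with a stage-tagged
#' error; intermediates (`indexes.csv`, `labels.csv`) and the report bundle
#' are plain CSV/PNG/JSON so each stage can be inspected and re-run.
#'
#' @param config A [run_config()] (or path to a YAML for
#'   [read_run_config()]).
#' @return Invisibly, a list with `units`, `comparisons` and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- run_stage("input", {
    m <- readr::read_csv(file.path(config$data_dir, "manifest.csv"),
                         show_col_types = FALSE)
    need <- c("recording_id", "treatment", "date", "period", "start_ts",
              "duration_s", "frames_dir")
    if (!all(need %in% names(m)))
      stop_input(paste("manifest.csv must have columns:", paste(need, collapse = ", ")))
    m
  })
  message("[segment/index] ", nrow(manifest), " recordings")
  indexes <- run_stage("segment/index", {
    dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
      rec <- manifest[i, ]
      frames <- read_frame_dir(file.path(config$data_dir, rec$frames_dir))
      shapes <- segment_frames(frames, sigma_px = config$sigma_px,
                               method = config$method, threshold = config$threshold,
                               polarity = config$polarity, min_area = config$min_area)
      idx <- suppressMessages(index_series(shapes, config$camera,
                                           variant = config$variant))
      dplyr::mutate(idx, recording_id = rec$recording_id,
                    treatment = rec$treatment, date = rec$date,
                    period = rec$period, .before = 1)
    }))
  })
  readr::write_csv(indexes, file.path(config$out_dir, "indexes.csv"))
  message("[thermal] labeling recording windows")
  labels <- run_stage("thermal", {
    log_ <- read_thermal_log(file.path(config$data_dir, "thermal.csv"))
    hourly <- hourly_means(log_)
    windows <- tibble::tibble(
      recording_id = manifest$recording_id,
      start = as.POSIXct(manifest$start_ts, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%d %H:%M:%S")),
      end = start + manifest$duration_s
    )
    label_recordings(windows, hourly, config$thresholds, config$rule)
  })
  readr::write_csv(labels, file.path(config$out_dir, "labels.csv"))
  units <- run_stage("aggregate", aggregate_units(indexes, labels))
  message("[report] ", nrow(units), " observation units")
  rep_cfg <- config[c("sigma_px", "method", "polarity", "min_area", "variant",
                      "rule", "alpha")]
  rep_cfg$camera <- unclass(config$camera)
  rep_cfg$thresholds <- unclass(config$thresholds)
  out <- run_stage("report",
                   report(units, config$out_dir, config = rep_cfg,
                          seed = config$seed, alpha = config$alpha))
  invisible(c(out, list(units = units,
                        indexes_csv = file.path(config$out_dir, "indexes.csv"),
                        labels_csv = file.path(config$out_dir, "labels.csv"))))
}
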