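#' Configuration for the synthetic flock simulator
#'
#' Defines an agent-based flock: `n_birds` point agents on a rectangular
#' floor of `arena_w` x `arena_h` pixels, each taking one first-order step
#' per output frame (1-s cadence at the default `fps_out = 1`):
#' `new = old + beta * (attractor - old) + N(0, sigma^2 I)`, reflected at the
#' arena walls. `step_sigma` is the motility ground truth behind the unrest
#' index; `attraction_beta` pulls birds toward `attractor_xy` (a feeder
#' stand-in) and is the ground truth behind the cluster index. Birds are
#' rendered as filled ellipses with semi-axes `bird_semi_axes`, orientation
#' drawn uniformly per bird per frame.
#'
#' @param n_birds Number of birds (default 20, one housed group).
#' @param arena_w,arena_h Arena width and height in px (default 352 x 240,
#'   the frame size of the analogue overhead cameras this emulates).
#' @param step_sigma Per-step Gaussian step scale, px/s; `>= 0`.
#' @param attraction_beta Per-second pull toward the attractor, in `[0, 1]`.
#' @param attractor_xy Attractor position `c(x, y)` in px.
#' @param bird_semi_axes Ellipse semi-axes `c(a, b)` in px. The default
#'   (12, 8) gives ~7% floor coverage for 20 birds, a sparseness comparable
#'   to segmented overhead footage of a small floor pen.
#' @param duration_s Simulated duration in seconds.
#' @param fps_out Output frames per second (default 1).
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A `flock_sim_config` list.
#' @export
flock_sim_config <- function(n_birds = 20, arena_w = 352, arena_h = 240,
                             step_sigma = 5, attraction_beta = 0,
                             attractor_xy = c(176, 120),
                             bird_semi_axes = c(12, 8),
                             duration_s = 60, fps_out = 1, seed = 1L) {
  if (!is_count(n_birds) || n_birds < 1) stop_config("n_birds must be a positive integer")
  if (!is.numeric(step_sigma) || step_sigma < 0) stop_config("step_sigma must be >= 0")
  if (!is.numeric(attraction_beta) || attraction_beta < 0 || attraction_beta > 1)
    stop_config("attraction_beta must lie in [0, 1]")
  if (length(bird_semi_axes) != 2 || any(bird_semi_axes <= 0))
    stop_config("bird_semi_axes must be two positive numbers")
  if (arena_w < 2 * bird_semi_axes[1] || arena_h < 2 * bird_semi_axes[2])
    stop_config("arena dimensions must be at least twice the bird semi-axes")
  if (!is.numeric(duration_s) || duration_s < 0) stop_config("duration_s must be >= 0")
  if (!is.numeric(fps_out) || fps_out <= 0) stop_config("fps_out must be > 0")
  structure(list(
    n_birds = as.integer(n_birds), arena_w = arena_w, arena_h = arena_h,
    step_sigma = step_sigma, attraction_beta = attraction_beta,
    attractor_xy = attractor_xy, bird_semi_axes = bird_semi_axes,
    duration_s = duration_s, fps_out = fps_out, seed = as.integer(seed)
  ), class = "flock_sim_config")
}

#' Simulate flock trajectories
#'
#' Runs the first-order dynamics of [flock_sim_config()] and returns one row
#' per bird per frame. Positions are continuous, 0-based pixel coordinates;
#' wall collisions are handled by reflection so the step scale is not
#' attenuated near walls. Frame 0 holds the uniformly drawn initial
#' positions (kept one semi-axis away from the walls).
#'
#' @param config A [flock_sim_config()].
#' @return A tibble with columns `frame` (0-based), `ts_s`, `bird_id`,
#'   `x_px`, `y_px`; `duration_s * fps_out + 1` frames in total.
#' @export
simulate_flock <- function(config) {
  stopifnot(inherits(config, "flock_sim_config"))
  set.seed(config$seed)
  n <- config$n_birds
  n_frames <- as.integer(round(config$duration_s * config$fps_out)) + 1L
  ax <- config$bird_semi_axes[1]; ay <- config$bird_semi_axes[2]
  x <- runif(n, ax, config$arena_w - 1 - ax)
  y <- runif(n, ay, config$arena_h - 1 - ay)
  xs <- matrix(NA_real_, n_frames, n)
  ys <- matrix(NA_real_, n_frames, n)
  xs[1, ] <- x; ys[1, ] <- y
  beta <- config$attraction_beta
  sig <- config$step_sigma
  att <- config$attractor_xy
  if (n_frames > 1) {
    for (f in 2:n_frames) {
      x <- x + beta * (att[1] - x) + rnorm(n, 0, sig)
      y <- y + beta * (att[2] - y) + rnorm(n, 0, sig)
      x <- reflect_into(x, 0, config$arena_w - 1)
      y <- reflect_into(y, 0, config$arena_h - 1)
      xs[f, ] <- x; ys[f, ] <- y
    }
  }
  out <- tibble::tibble(
    frame = rep(seq_len(n_frames) - 1L, each = n),
    ts_s = rep((seq_len(n_frames) - 1) / config$fps_out, each = n),
    bird_id = rep(seq_len(n), times = n_frames),
    x_px = as.vector(t(xs)),
    y_px = as.vector(t(ys))
  )
  attr(out, "config") <- config
  out
}

# fill one ellipse into an integer mask matrix (rows = y, cols = x, 0-based)
rasterize_ellipse <- function(mask, cx, cy, a, b, theta) {
  h <- nrow(mask); w <- ncol(mask)
  r <- max(a, b)
  c0 <- max(0, floor(cx - r)); c1 <- min(w - 1, ceiling(cx + r))
  r0 <- max(0, floor(cy - r)); r1 <- min(h - 1, ceiling(cy + r))
  if (c0 > c1 || r0 > r1) return(mask)
  xs <- c0:c1; ys <- r0:r1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  sub <- mask[ys + 1, xs + 1, drop = FALSE]
  sub[u^2 + v^2 <= 1] <- 1L
  mask[ys + 1, xs + 1] <- sub
  mask
}

#' Render trajectories as binary frame masks
#'
#' Draws every bird of every frame as a filled ellipse; overlapping birds
#' merge into a single connected blob, as threshold segmentation of real
#' top-view footage would produce. Ellipse orientation is sampled uniformly
#' per bird per frame (seeded), so blob shape varies without a posture model.
#'
#' @param traj Trajectory tibble from [simulate_flock()].
#' @param config The matching [flock_sim_config()].
#' @param seed Seed for the orientation draws; defaults to `config$seed + 1`
#'   so simulate + render is reproducible as a pair.
#' @param orientation `"per_frame"` (default): each bird's orientation is
#'   redrawn every frame, stressing the area/perimeter measurements;
#'   `"per_bird"`: one orientation per bird held for the whole recording, so
#'   a motionless flock renders bit-identical frames.
#' @return List of integer 0/1 matrices (`arena_h` x `arena_w`), each with
#'   attributes `frame` and `ts_s`, class `frame_mask`.
#' @export
render_frames <- function(traj, config, seed = config$seed + 1L,
                          orientation = c("per_frame", "per_bird")) {
  stopifnot(inherits(config, "flock_sim_config"))
  orientation <- match.arg(orientation)
  if (any(traj$x_px < 0 | traj$x_px > config$arena_w - 1 |
          traj$y_px < 0 | traj$y_px > config$arena_h - 1))
    stop_input("trajectory contains centers outside the arena")
  set.seed(seed)
  a <- config$bird_semi_axes[1]; b <- config$bird_semi_axes[2]
  fixed_th <- runif(config$n_birds, 0, pi)
  frames <- split(traj, traj$frame)
  lapply(frames, function(fr) {
    mask <- matrix(0L, config$arena_h, config$arena_w)
    th <- if (orientation == "per_frame") runif(nrow(fr), 0, pi)
          else fixed_th[fr$bird_id]
    for (i in seq_len(nrow(fr)))
      mask <- rasterize_ellipse(mask, fr$x_px[i], fr$y_px[i], a, b, th[i])
    structure(mask, frame = fr$frame[1], ts_s = fr$ts_s[1], class = "frame_mask")
  })
}

#' Write frame masks as 8-bit PNG files
#'
#' Files are named `frame_%06d.png` from each mask's `frame` attribute;
#' foreground is 255, background 0.
#'
#' @param masks List of masks from [render_frames()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_frame_masks <- function(masks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(masks, function(m) {
    p <- file.path(dir, sprintf("frame_%06d.png", as.integer(attr(m, "frame"))))
    png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), p)
    p
  }, character(1))
  invisible(paths)
}

#' Write a trajectory as CSV
#'
#' Columns `timestamp` (ISO-8601, UTC), `bird_id`, `x_px`, `y_px`.
#'
#' @param traj Trajectory tibble from [simulate_flock()].
#' @param path Output CSV path.
#' @param start Start time (POSIXct) of frame 0.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path,
                                 start = as.POSIXct("2020-06-10 08:00:00", tz = "UTC")) {
  out <- tibble::tibble(
    timestamp = format(start + traj$ts_s, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    bird_id = traj$bird_id, x_px = traj$x_px, y_px = traj$y_px
  )
  readr::write_csv(out, path)
  invisible(path)
}

# per-class (T, RH) boxes; each box keeps the hourly-mean THI strictly inside
# its class with margin to the 59/78 limits
thermal_class_boxes <- list(
  cold    = list(t = c(6, 13),    rh = c(40, 90)),
  comfort = list(t = c(20, 26),   rh = c(50, 80)),
  heat    = list(t = c(30.5, 34), rh = c(55, 80))
)

#' Simulate a datalogger thermal series with scheduled comfort classes
#'
#' Emulates a temperature/relative-humidity logger sampling every 5 minutes
#' (12 records per hour). Each hour is assigned a target comfort class; a
#' base (T, RH) pair is drawn from a class-specific box chosen so that the
#' hourly-mean THI falls strictly inside the scheduled class, then per-record
#' jitter is added.
#'
#' @param hours Number of hours to simulate.
#' @param regime_schedule Character vector of length `hours` with values
#'   `"cold"`, `"comfort"` or `"heat"`.
#' @param seed Integer seed.
#' @param start POSIXct start of the first hour.
#' @return Tibble with `timestamp`, `temp_c`, `rh_pct` (`12 * hours` rows).
#' @export
simulate_thermal <- function(hours, regime_schedule, seed = 1L,
                             start = as.POSIXct("2020-06-10 00:00:00", tz = "UTC")) {
  if (!is_count(hours) || hours < 1) stop_config("hours must be a positive integer")
  if (length(regime_schedule) != hours)
    stop_config("regime_schedule must have one class per hour")
  bad <- setdiff(unique(regime_schedule), names(thermal_class_boxes))
  if (length(bad))
    stop_config(paste0("unreachable comfort class in schedule: ", paste(bad, collapse = ", ")))
  set.seed(seed)
  recs <- lapply(seq_len(hours), function(h) {
    box <- thermal_class_boxes[[regime_schedule[h]]]
    t0 <- runif(1, box$t[1], box$t[2])
    rh0 <- runif(1, box$rh[1], box$rh[2])
    tibble::tibble(
      timestamp = start + (h - 1) * 3600 + (0:11) * 300,
      temp_c = t0 + rnorm(12, 0, 0.15),
      rh_pct = pmin(100, pmax(0, rh0 + rnorm(12, 0, 0.8)))
    )
  })
  dplyr::bind_rows(recs)
}

#' Write a thermal series as CSV
#'
#' Columns `timestamp` (ISO-8601, UTC), `temp_c`, `rh_pct`.
#'
#' @param records Tibble from [simulate_thermal()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_thermal_csv <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}
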