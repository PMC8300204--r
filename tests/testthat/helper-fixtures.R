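# fixtures built in code; no files on disk

# binary mask with a filled axis-aligned rectangle (0-based corner, size)
square_mask <- function(h = 30, w = 30, x0 = 5, y0 = 5, side = 10) {
  m <- matrix(0L, h, w)
  m[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side)] <- 1L
  m
}

# toy two-blob shape table used by the cluster-index oracle
toy_two_blobs <- function() {
  tibble::tibble(area_px2 = c(100, 100), perimeter_px = c(40, 40),
                 cx_px = c(0, 30), cy_px = c(0, 40))
}

# brute-force double-loop oracles (kept deliberately naive)
oracle_mean_pairwise <- function(xy) {
  n <- nrow(xy); tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sqrt(sum((xy[i, ] - xy[j, ])^2)); cnt <- cnt + 1
  }
  tot / cnt
}
oracle_directed_hausdorff <- function(a, b) {
  worst <- 0
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    worst <- max(worst, best)
  }
  worst
}

# per-recording mean unrest straight from a trajectory (centroids = centers),
# bypassing rendering; used where only the statistic's sampling distribution
# matters, not the imaging chain
traj_mean_unrest <- function(cfg, k = pixel_to_cm_factor(camera_geometry())) {
  traj <- simulate_flock(cfg)
  fr <- split(traj, traj$frame)
  vals <- vapply(seq_len(length(fr) - 1), function(i) {
    unrest_index(cbind(fr[[i]]$x_px, fr[[i]]$y_px),
                 cbind(fr[[i + 1]]$x_px, fr[[i + 1]]$y_px), k)
  }, numeric(1))
  mean(vals)
}

# render a config and push it through the measurement chain to an index series
sim_index_series <- function(cfg, variant = "n_minus_1", min_area = 50,
                             orientation = "per_frame") {
  traj <- simulate_flock(cfg)
  masks <- render_frames(traj, cfg, orientation = orientation)
  shapes <- segment_frames(masks, sigma_px = 0, method = "fixed",
                           threshold = 0.5, min_area = min_area)
  suppressMessages(index_series(shapes, camera_geometry(), variant = variant))
}
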