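#' Overhead camera geometry
#'
#' Geometry of the ceiling-mounted camera, used to convert pixel distances
#' on the floor plane to centimetres. Defaults match an analogue CCD
#' surveillance camera mounted 1.5 m above the floor with a 60 degree
#' viewing angle and a 352-px-wide frame.
#'
#' @param height_cm Camera height above the floor, cm (> 0).
#' @param alpha_deg Lens opening angle, degrees, in (0, 180).
#' @param sensor_w_px Frame width in px (>= 1), the longest frame dimension.
#' @return A `camera_geometry` object.
#' @export
camera_geometry <- function(height_cm = 150, alpha_deg = 60, sensor_w_px = 352) {
  if (!is.numeric(height_cm) || height_cm < 0) stop_input("height_cm must be >= 0")
  if (!is.numeric(alpha_deg) || alpha_deg <= 0 || alpha_deg >= 180)
    stop_input("alpha_deg must lie in (0, 180)")
  if (!is.numeric(sensor_w_px) || sensor_w_px < 1) stop_input("sensor_w_px must be >= 1")
  structure(list(height_cm = height_cm, alpha_deg = alpha_deg,
                 sensor_w_px = sensor_w_px), class = "camera_geometry")
}

#' Pixel-to-centimetre proportionality factor
#'
#' The ground width seen by the camera is `2 * H * tan(alpha / 2)`; divided
#' by the sensor width in pixels it gives the floor-plane scale
#' `k = 2 * H * tan(alpha / 2) / w` in cm per pixel, which converts the
#' Hausdorff displacement of the unrest index to centimetres.
#'
#' @param geom A [camera_geometry()].
#' @return k in cm/px.
#' @export
pixel_to_cm_factor <- function(geom) {
  stopifnot(inherits(geom, "camera_geometry"))
  2 * geom$height_cm * tan(geom$alpha_deg * pi / 360) / geom$sensor_w_px
}

#' Mean pairwise distance between centroids
#'
#' Mean Euclidean distance over all unordered pairs of points; the D-bar
#' term of the cluster index. Undefined (NA with a warning suppressed by
#' callers that flag the frame invalid) for fewer than two points.
#'
#' @param xy Two-column matrix (x, y) of centroid coordinates in px.
#' @return Mean pair distance in px, or `NA_real_` if fewer than 2 points.
#' @export
mean_pairwise_distance <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) return(NA_real_)
  mean(dist(xy))
}

#' Directed Hausdorff distance between point sets
#'
#' `max` over points of `a` of the distance to the nearest point of `b`.
#' Asymmetric; the symmetric unrest form takes the max of both directions.
#'
#' @param a,b Two-column matrices of points in px; both nonempty.
#' @return Distance in px, or `NA_real_` if either set is empty.
#' @export
directed_hausdorff <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) return(NA_real_)
  # coordinate differences, not the expanded quadratic form, so identical
  # points give an exact zero
  worst <- 0
  for (i in seq_len(nrow(a)))
    worst <- max(worst, min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2))
  sqrt(worst)
}

#' Per-frame cluster index
#'
#' Combines the mean blob area `A` and perimeter `P` (px), the mean
#' inter-centroid distance `D` (px), the cropped-frame diagonal
#' `sqrt(h^2 + w^2)` and the blob count `nA` into a single agglomeration
#' statistic; higher values mean a tighter flock. Two readings of the blob
#' count term are in circulation, so both are implemented:
#'
#' * `variant = "n_minus_1"` (default): `2 * A * sqrt(h^2 + w^2) / (P * D * (nA - 1))`
#' * `variant = "n_inverse"`: `2 * A * sqrt(h^2 + w^2) / (P * D * nA)`
#'
#' The variant used is carried through all outputs. The index is a unitful
#' pixel-scaled ratio; no normalization is applied beyond the formula.
#'
#' @param shapes Blob table with `area_px2`, `perimeter_px`, `cx_px`,
#'   `cy_px` (one frame's rows of [segment_frames()] output).
#' @param h,w Height and width in px of the cropped frame.
#' @param variant `"n_minus_1"` or `"n_inverse"`.
#' @return The index, or `NA_real_` when a term is undefined (`nA <= 1`
#'   under `n_minus_1`; `nA == 0`, or `nA == 1` where the mean pair distance
#'   does not exist, under `n_inverse`). No numeric value is fabricated for
#'   such frames; callers flag them invalid.
#' @export
cluster_index <- function(shapes, h, w, variant = c("n_minus_1", "n_inverse")) {
  variant <- match.arg(variant)
  n <- nrow(shapes)
  if (is.null(n) || n < 2) return(NA_real_)
  dbar <- mean_pairwise_distance(cbind(shapes$cx_px, shapes$cy_px))
  abar <- mean(shapes$area_px2)
  pbar <- mean(shapes$perimeter_px)
  denom_n <- if (variant == "n_minus_1") n - 1 else n
  2 * abar * sqrt(h^2 + w^2) / (pbar * dbar * denom_n)
}

#' Per-second unrest index
#'
#' Symmetric Hausdorff distance between the blob-centroid sets of two
#' frames recorded 1 s apart, scaled to centimetres by the camera factor
#' `k`: `k * max(dH(cur, prev), dH(prev, cur))`. Zero iff the two centroid
#' sets are equal as sets; higher values mean more flock movement.
#'
#' @param centroids_prev,centroids_cur Two-column matrices of centroids in
#'   px for the earlier and later frame.
#' @param k Scale factor in cm/px from [pixel_to_cm_factor()].
#' @return Unrest in cm, or `NA_real_` if either frame has no centroids.
#' @export
unrest_index <- function(centroids_prev, centroids_cur, k) {
  d1 <- directed_hausdorff(centroids_cur, centroids_prev)
  d2 <- directed_hausdorff(centroids_prev, centroids_cur)
  if (is.na(d1) || is.na(d2)) return(NA_real_)
  k * max(d1, d2)
}

#' Compute the per-frame index series for one recording
#'
#' Assembles, from a blob-shape table, one record per frame: blob count,
#' mean area/perimeter, mean pair distance, the cluster index, and -- for
#' every consecutive 1-s frame pair -- the unrest index. Frames where a
#' formula term is undefined are flagged `valid = FALSE`, never dropped;
#' missing or invalid frames break the unrest pairing (no interpolation).
#'
#' @param shapes Tibble from [segment_frames()] (columns `frame`, `ts_s`,
#'   `blob_id`, `area_px2`, `perimeter_px`, `cx_px`, `cy_px`).
#' @param geom A [camera_geometry()].
#' @param h,w Cropped-frame dimensions; default from the `h`/`w` attributes
#'   of `shapes`.
#' @param variant Cluster-index variant, see [cluster_index()].
#' @param frames Optional tibble (`frame`, `ts_s`) enumerating all frames of
#'   the recording, so frames with no blobs still yield (invalid) records;
#'   defaults to the `frames` attribute of `shapes`, else to the frames
#'   present in the table. Must be sorted with unique frame indices.
#' @return Tibble with `frame`, `ts_s`, `n_clusters`, `mean_area_px2`,
#'   `mean_perimeter_px`, `mean_pair_dist_px`, `cluster_index`,
#'   `unrest_index_cm`, `valid`; attribute `variant`.
#' @export
index_series <- function(shapes, geom, h = attr(shapes, "h"), w = attr(shapes, "w"),
                         variant = c("n_minus_1", "n_inverse"), frames = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(geom, "camera_geometry"))
  if (is.null(h) || is.null(w)) stop_input("cropped frame dimensions h and w are required")
  if (is.null(frames)) frames <- attr(shapes, "frames")
  if (is.null(frames))
    frames <- dplyr::distinct(shapes[order(shapes$frame), c("frame", "ts_s")])
  if (any(duplicated(frames$frame)) || is.unsorted(frames$frame, strictly = TRUE))
    stop_input("frame indices must be strictly increasing and unique")
  k <- pixel_to_cm_factor(geom)
  by_frame <- split(shapes, factor(shapes$frame, levels = frames$frame))
  recs <- lapply(seq_len(nrow(frames)), function(i) {
    shp <- by_frame[[i]]
    n <- if (is.null(shp)) 0L else nrow(shp)
    tibble::tibble(
      frame = frames$frame[i],
      ts_s = frames$ts_s[i],
      n_clusters = n,
      mean_area_px2 = if (n) mean(shp$area_px2) else NA_real_,
      mean_perimeter_px = if (n) mean(shp$perimeter_px) else NA_real_,
      mean_pair_dist_px = if (n >= 2) mean_pairwise_distance(cbind(shp$cx_px, shp$cy_px)) else NA_real_,
      cluster_index = if (n) cluster_index(shp, h, w, variant) else NA_real_
    )
  })
  out <- dplyr::bind_rows(recs)
  out$valid <- !is.na(out$cluster_index)
  cents <- lapply(by_frame, function(shp)
    if (is.null(shp) || !nrow(shp)) NULL else cbind(shp$cx_px, shp$cy_px))
  unrest <- rep(NA_real_, nrow(out))
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      consecutive <- out$frame[i] - out$frame[i - 1] == 1
      if (consecutive && !is.null(cents[[i - 1]]) && !is.null(cents[[i]]))
        unrest[i] <- unrest_index(cents[[i - 1]], cents[[i]], k)
    }
  }
  out$unrest_index_cm <- unrest
  n_invalid <- sum(!out$valid)
  if (n_invalid) message(n_invalid, " of ", nrow(out), " frames flagged invalid")
  out <- out[, c("frame", "ts_s", "n_clusters", "mean_area_px2", "mean_perimeter_px",
                 "mean_pair_dist_px", "cluster_index", "unrest_index_cm", "valid")]
  attr(out, "variant") <- variant
  out
}

#' Write an index series as CSV
#'
#' @param indexes Tibble from [index_series()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_indexes_csv <- function(indexes, path) {
  readr::write_csv(indexes, path)
  invisible(path)
}
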