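#' Region of interest polygon
#'
#' A polygon (in 0-based pixel coordinates, x = column, y = row) delimiting
#' the object-free floor area inside which all measurements are taken. The
#' same polygon is applied to every frame of a recording.
#'
#' @param x,y Numeric vectors of vertex coordinates (>= 3 vertices).
#' @return A `roi_polygon` object.
#' @export
roi_polygon <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_input("a ROI polygon needs at least 3 (x, y) vertices")
  structure(list(x = as.numeric(x), y = as.numeric(y)), class = "roi_polygon")
}

#' Crop a frame to a region of interest
#'
#' Pixels whose centres fall outside the polygon are set to `bg`; the result
#' is cropped to the polygon's bounding box. The crop offset is recorded in
#' attributes `x_offset` / `y_offset` so centroids measured in the cropped
#' frame can be mapped back to full-frame coordinates.
#'
#' @param frame Numeric matrix (grayscale, rows = y, cols = x).
#' @param roi A [roi_polygon()], or `NULL` for no cropping.
#' @param bg Background value for outside-ROI pixels (default 0).
#' @return Cropped matrix with `x_offset`, `y_offset` attributes.
#' @export
crop_roi <- function(frame, roi = NULL, bg = 0) {
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(roi)) {
    attr(frame, "x_offset") <- 0L
    attr(frame, "y_offset") <- 0L
    return(frame)
  }
  stopifnot(inherits(roi, "roi_polygon"))
  # vertices may extend half a pixel beyond the outermost pixel centres
  if (any(roi$x < -0.5 | roi$x > w - 0.5 | roi$y < -0.5 | roi$y > h - 0.5))
    stop_input("ROI polygon extends outside the frame")
  c0 <- max(0L, as.integer(ceiling(min(roi$x))))
  c1 <- min(w - 1L, as.integer(floor(max(roi$x))))
  r0 <- max(0L, as.integer(ceiling(min(roi$y))))
  r1 <- min(h - 1L, as.integer(floor(max(roi$y))))
  xs <- c0:c1; ys <- r0:r1
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  bnd <- cbind(c(roi$x, roi$x[1]), c(roi$y, roi$y[1]))
  inside <- mgcv::in.out(bnd, pts)
  sub <- frame[ys + 1, xs + 1, drop = FALSE]
  sub[!matrix(inside, length(ys), length(xs))] <- bg
  attr(sub, "x_offset") <- c0
  attr(sub, "y_offset") <- r0
  sub
}

#' Gaussian low-pass filter
#'
#' Smooths a grayscale frame with an isotropic Gaussian kernel, using
#' reflective borders (the frame is reflect-padded by the kernel radius
#' before filtering). `sigma_px = 0` returns the frame unchanged.
#'
#' @param frame Numeric matrix.
#' @param sigma_px Gaussian standard deviation in px; `>= 0`.
#' @return Filtered matrix of the same dimensions.
#' @export
lowpass <- function(frame, sigma_px) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || sigma_px < 0)
    stop_input("sigma_px must be a single number >= 0")
  if (sigma_px == 0) return(frame)
  h <- nrow(frame); w <- ncol(frame)
  pad <- 2L * as.integer(ceiling(3 * sigma_px)) + 2L
  ridx <- round(reflect_into(seq(1 - pad, h + pad), 1, h))
  cidx <- round(reflect_into(seq(1 - pad, w + pad), 1, w))
  padded <- frame[ridx, cidx, drop = FALSE]
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(padded), sigma = sigma_px))
  out <- sm[pad + seq_len(h), pad + seq_len(w), drop = FALSE]
  attributes(out) <- attributes(frame)[c("dim", "x_offset", "y_offset")]
  out
}

#' Binarize a frame into a bird mask
#'
#' Thresholds a grayscale frame so that only the birds are foreground.
#' `method = "otsu"` picks the threshold maximizing between-class variance;
#' `method = "fixed"` uses the supplied `threshold` on the 0-255 scale.
#' `polarity` states whether birds are brighter or darker than the floor
#' (this differs between recordings; there is no universal default for real
#' footage, bright birds are assumed unless told otherwise).
#'
#' @param frame Numeric matrix with values in `[0, 255]`.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold in `[0, 255]`; required for `method = "fixed"`.
#' @param polarity `"bright_birds"` (foreground above threshold) or
#'   `"dark_birds"` (below).
#' @return Integer 0/1 matrix of class `frame_mask` with attribute
#'   `threshold` (the value used).
#' @export
binarize <- function(frame, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("bright_birds", "dark_birds")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  if (method == "fixed") {
    if (is.null(threshold)) stop_config("method = \"fixed\" requires a threshold")
    if (threshold < 0 || threshold > 255) stop_config("threshold must lie in [0, 255]")
    thr <- threshold
  } else {
    thr <- 255 * EBImage::otsu(EBImage::Image(frame / 255), range = c(0, 1), levels = 256)
  }
  mask <- if (polarity == "bright_birds") frame > thr else frame < thr
  structure(matrix(as.integer(mask), nrow(frame), ncol(frame)),
            threshold = thr, class = "frame_mask")
}

# number of foreground 4-neighbours of every pixel (zero-padded borders)
fg_neighbour_count <- function(m) {
  h <- nrow(m); w <- ncol(m)
  n <- matrix(0L, h, w)
  n[-h, ] <- n[-h, ] + m[-1, ]
  n[-1, ] <- n[-1, ] + m[-h, ]
  n[, -w] <- n[, -w] + m[, -1]
  n[, -1] <- n[, -1] + m[, -w]
  n
}

#' Label connected blobs and measure them
#'
#' Finds 8-connected components of a binary mask and returns one row per
#' blob with area (pixel count), perimeter (count of pixel edges between
#' foreground and background, including frame borders and hole boundaries)
#' and centroid (mean pixel coordinates, 0-based). Components smaller than
#' `min_area` are discarded; their total area is recorded in the
#' `dropped_area` attribute so foreground area is conserved.
#'
#' @param mask Integer/logical 0-1 matrix (e.g. from [binarize()]).
#' @param min_area Minimum blob area in px^2 (default 50, a noise floor for
#'   352 x 240 frames).
#' @return Tibble with `blob_id`, `area_px2`, `perimeter_px`, `cx_px`,
#'   `cy_px`; attributes `h`, `w`, `dropped_area`. An empty mask yields an
#'   empty tibble.
#' @export
label_components <- function(mask, min_area = 50) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  h <- nrow(m); w <- ncol(m)
  fg <- which(m == 1L)
  empty <- tibble::tibble(blob_id = integer(), area_px2 = numeric(),
                          perimeter_px = numeric(), cx_px = numeric(), cy_px = numeric())
  attr(empty, "h") <- h; attr(empty, "w") <- w; attr(empty, "dropped_area") <- 0
  if (!length(fg)) return(empty)
  vid <- integer(h * w)
  vid[fg] <- seq_along(fg)
  rw <- (fg - 1L) %% h + 1L
  cl <- (fg - 1L) %/% h + 1L
  edges <- integer(0)
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nr <- rw + sh[1]; nc <- cl + sh[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    nv <- vid[nidx]
    hit <- nv > 0L
    if (any(hit)) edges <- c(edges, rbind(vid[fg[ok]][hit], nv[hit]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  area <- tabulate(comp)
  edge_px <- 4L - fg_neighbour_count(m)[fg]
  perim <- as.vector(rowsum(as.numeric(edge_px), comp))
  cx <- as.vector(rowsum(as.numeric(cl - 1L), comp)) / area
  cy <- as.vector(rowsum(as.numeric(rw - 1L), comp)) / area
  first_px <- vapply(split(fg, comp), min, numeric(1))
  keep <- which(area >= min_area)
  keep <- keep[order(first_px[keep])]
  out <- tibble::tibble(
    blob_id = seq_along(keep),
    area_px2 = area[keep],
    perimeter_px = perim[keep],
    cx_px = cx[keep],
    cy_px = cy[keep]
  )
  attr(out, "h") <- h; attr(out, "w") <- w
  attr(out, "dropped_area") <- sum(area) - sum(area[keep])
  out
}

#' Read a directory of grayscale frames
#'
#' Reads PNG (and TIFF, if the tiff package is installed) frames in natural
#' sort order (numeric runs in file names compared as numbers) and returns
#' them as matrices on the 0-255 scale.
#'
#' @param dir Directory containing `*.png` / `*.tif(f)` frames.
#' @return Named list of numeric matrices.
#' @export
read_frame_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  if (!length(files)) stop_input(paste0("no frames found in ", dir))
  num <- suppressWarnings(as.numeric(sub("^.*?(\\d+)\\D*$", "\\1", files)))
  files <- files[order(is.na(num), num, files)]
  frames <- lapply(file.path(dir, files), function(p) {
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      img <- png::readPNG(p)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_input("the tiff package is required to read TIFF frames")
      img <- tiff::readTIFF(p)
    }
    if (length(dim(img)) == 3) img <- img[, , 1]
    img * 255
  })
  names(frames) <- files
  frames
}

#' Segment a frame sequence into a blob-shape table
#'
#' Applies the full measurement chain -- ROI crop, Gaussian low-pass,
#' threshold, 8-connected labeling with a minimum-area filter -- to every
#' frame and stacks the per-blob measurements.
#'
#' @param frames List of grayscale matrices (0-255), e.g. from
#'   [read_frame_dir()], or of binary `frame_mask` matrices.
#' @param roi Optional [roi_polygon()] applied to every frame.
#' @param sigma_px Low-pass sigma in px (0 disables smoothing).
#' @param method,threshold,polarity Passed to [binarize()].
#' @param min_area Passed to [label_components()].
#' @param timestamps Optional numeric vector of frame times in seconds;
#'   defaults to 0, 1, 2, ... (1 fps).
#' @return Tibble with `frame` (0-based), `ts_s`, `blob_id`, `area_px2`,
#'   `perimeter_px`, `cx_px`, `cy_px`; attributes `h`, `w` give the cropped
#'   frame size consumed by the cluster index.
#' @export
segment_frames <- function(frames, roi = NULL, sigma_px = 1,
                           method = "otsu", threshold = NULL,
                           polarity = "bright_birds", min_area = 50,
                           timestamps = NULL) {
  if (is.null(timestamps)) timestamps <- seq_along(frames) - 1
  if (length(timestamps) != length(frames))
    stop_input("timestamps must have one entry per frame")
  dims <- NULL
  rows <- lapply(seq_along(frames), function(i) {
    fr <- crop_roi(frames[[i]], roi)
    fr <- lowpass(fr, sigma_px)
    mask <- binarize(fr, method = method, threshold = threshold, polarity = polarity)
    shp <- label_components(mask, min_area = min_area)
    dims <<- c(attr(shp, "h"), attr(shp, "w"))
    if (nrow(shp)) shp <- dplyr::mutate(shp, frame = i - 1L, ts_s = timestamps[i], .before = 1)
    shp
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    out <- tibble::tibble(frame = integer(), ts_s = numeric(), blob_id = integer(),
                          area_px2 = numeric(), perimeter_px = numeric(),
                          cx_px = numeric(), cy_px = numeric())
  attr(out, "h") <- dims[1]; attr(out, "w") <- dims[2]
  attr(out, "frames") <- tibble::tibble(frame = seq_along(frames) - 1L, ts_s = timestamps)
  out
}

#' Write a blob-shape table as CSV
#'
#' @param shapes Tibble from [segment_frames()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_shapes_csv <- function(shapes, path) {
  readr::write_csv(shapes, path)
  invisible(path)
}
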