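test_that("pixel-to-cm factor follows the camera geometry", {
  expect_equal(pixel_to_cm_factor(camera_geometry(150, 60, 352)),
               300 * tan(pi / 6) / 352, tolerance = 1e-12)
  expect_equal(pixel_to_cm_factor(camera_geometry(0, 60, 352)), 0)
  k1 <- pixel_to_cm_factor(camera_geometry(100, 60, 352))
  k2 <- pixel_to_cm_factor(camera_geometry(200, 60, 352))
  expect_equal(k2, 2 * k1)
  expect_error(camera_geometry(alpha_deg = 180), class = "hensight_input_error")
})

test_that("mean pairwise distance matches hand values and the brute-force oracle", {
  expect_equal(mean_pairwise_distance(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(mean_pairwise_distance(rbind(c(0, 0), c(0, 3), c(0, 6))), 4)
  expect_true(is.na(mean_pairwise_distance(rbind(c(1, 1)))))
  set.seed(10)
  for (rep in 1:20) {
    xy <- matrix(runif(2 * sample(2:200, 1), 0, 352), ncol = 2)
    expect_equal(mean_pairwise_distance(xy), oracle_mean_pairwise(xy))
  }
})

test_that("directed Hausdorff is asymmetric and matches the double-loop oracle", {
  a <- rbind(c(0, 0), c(1, 0)); b <- rbind(c(0, 0))
  expect_equal(directed_hausdorff(a, b), 1)
  expect_equal(directed_hausdorff(b, a), 0)
  expect_equal(directed_hausdorff(a, a), 0)
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(runif(2 * sample(1:200, 1), 0, 300), ncol = 2)
    y <- matrix(runif(2 * sample(1:200, 1), 0, 300), ncol = 2)
    expect_equal(directed_hausdorff(x, y), oracle_directed_hausdorff(x, y))
  }
})

test_that("cluster index reproduces the two-blob hand computation", {
  shp <- toy_two_blobs()
  diag <- sqrt(240^2 + 352^2)
  expect_equal(cluster_index(shp, 240, 352, "n_minus_1"),
               2 * 100 * diag / (40 * 50 * 1), tolerance = 1e-12)
  expect_equal(cluster_index(shp, 240, 352, "n_inverse"),
               cluster_index(shp, 240, 352, "n_minus_1") / 2)
  # shrinking D-bar strictly increases the index
  closer <- shp; closer$cx_px <- c(0, 3); closer$cy_px <- c(0, 4)
  expect_gt(cluster_index(closer, 240, 352), cluster_index(shp, 240, 352))
})

test_that("cluster index marks undefined frames invalid instead of fabricating", {
  one <- toy_two_blobs()[1, ]
  expect_true(is.na(cluster_index(one, 240, 352, "n_minus_1")))
  expect_true(is.na(cluster_index(one, 240, 352, "n_inverse")))
  expect_true(is.na(cluster_index(toy_two_blobs()[0, ], 240, 352)))
})

test_that("cluster index is translation invariant and decreasing in nA", {
  set.seed(12)
  shp <- tibble::tibble(area_px2 = runif(6, 80, 150), perimeter_px = runif(6, 35, 60),
                        cx_px = runif(6, 0, 300), cy_px = runif(6, 0, 200))
  moved <- shp
  moved$cx_px <- moved$cx_px + 17.3
  moved$cy_px <- moved$cy_px - 4.2
  for (v in c("n_minus_1", "n_inverse"))
    expect_equal(cluster_index(moved, 240, 352, v), cluster_index(shp, 240, 352, v))
  # adding one more blob with identical morphometry at an existing centroid
  # leaves A, P unchanged and D-bar smaller-or-similar, but the nA term must
  # dominate comparisons at fixed A, P, D: check the explicit formula path
  for (v in c("n_minus_1", "n_inverse")) {
    f <- function(n) {
      sh <- tibble::tibble(area_px2 = 100, perimeter_px = 40,
                           cx_px = seq(0, 300, length.out = n),
                           cy_px = rep(0, n))
      denom <- if (v == "n_minus_1") n - 1 else n
      d <- mean_pairwise_distance(cbind(sh$cx_px, sh$cy_px))
      c(cluster_index(sh, 240, 352, v), 2 * 100 * sqrt(240^2 + 352^2) / (40 * d * denom))
    }
    for (n in c(3, 5, 9)) expect_equal(f(n)[1], f(n)[2])
  }
})

test_that("unrest index scales a rigid translation by k and is symmetric", {
  set.seed(13)
  prev <- matrix(runif(40, 0, 300), ncol = 2)
  cur <- sweep(prev, 2, c(3, 4), "+")
  expect_equal(unrest_index(prev, cur, 0.5), 2.5)
  expect_equal(unrest_index(cur, prev, 0.5), unrest_index(prev, cur, 0.5))
  expect_equal(unrest_index(prev, prev, 0.7), 0)
  expect_true(is.na(unrest_index(prev[0, , drop = FALSE], cur, 0.5)))
  # linear in k, hence in camera height
  expect_equal(unrest_index(prev, cur, 1.0), 2 * unrest_index(prev, cur, 0.5))
})

test_that("index_series assembles one record per frame and pairs 1-s frames", {
  cfg <- flock_sim_config(n_birds = 6, bird_semi_axes = c(6, 4),
                          step_sigma = 3, duration_s = 20, seed = 21)
  idx <- sim_index_series(cfg)
  expect_equal(nrow(idx), 21)
  expect_equal(sum(!is.na(idx$unrest_index_cm)), 20)
  expect_true(is.na(idx$unrest_index_cm[1]))
  expect_true(all(idx$unrest_index_cm >= 0, na.rm = TRUE))
  expect_identical(attr(idx, "variant"), "n_minus_1")
  # static flock rendered with held orientations: all unrest exactly 0
  cfg0 <- flock_sim_config(n_birds = 6, bird_semi_axes = c(6, 4),
                           step_sigma = 0, duration_s = 10, seed = 21)
  idx0 <- sim_index_series(cfg0, orientation = "per_bird")
  expect_true(all(idx0$unrest_index_cm[-1] == 0))
  expect_true(all(idx0$cluster_index == idx0$cluster_index[1]))
})

test_that("index_series flags missing frames invalid and breaks unrest pairs", {
  shp <- tibble::tibble(frame = c(0L, 0L, 2L, 2L), ts_s = c(0, 0, 2, 2),
                        blob_id = c(1L, 2L, 1L, 2L),
                        area_px2 = 100, perimeter_px = 40,
                        cx_px = c(0, 30, 1, 31), cy_px = c(0, 40, 0, 40))
  frames <- tibble::tibble(frame = 0:2, ts_s = 0:2)
  idx <- suppressMessages(index_series(shp, camera_geometry(), h = 240, w = 352,
                                       frames = frames))
  expect_equal(nrow(idx), 3)
  expect_false(idx$valid[2])
  expect_true(all(is.na(idx$unrest_index_cm)))  # no consecutive valid pair
  bad <- tibble::tibble(frame = c(1L, 0L), ts_s = c(1, 0))
  expect_error(index_series(shp, camera_geometry(), h = 240, w = 352, frames = bad),
               class = "hensight_input_error")
})

test_that("mean unrest grows with motility across seeded flocks", {
  k <- pixel_to_cm_factor(camera_geometry())
  means <- sapply(c(2, 8), function(sig) {
    mean(sapply(1:6, function(s) {
      traj_mean_unrest(flock_sim_config(step_sigma = sig, duration_s = 30,
                                        seed = 100 + s), k)
    }))
  })
  expect_gt(means[2], means[1])
})
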