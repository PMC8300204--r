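# build a units table directly: treatment x period x comfort cell means
make_units <- function(mus, n_per_cell = 6, sd = 1, seed = 1,
                       treatments = names(mus)) {
  set.seed(seed)
  grid <- tidyr::expand_grid(treatment = treatments,
                             period = c("morning", "afternoon"),
                             comfort = factor(c("comfort", "heat"),
                                              levels = c("cold", "comfort", "heat")),
                             rep = seq_len(n_per_cell))
  grid$recording_id <- sprintf("r%03d", seq_len(nrow(grid)))
  grid$date <- as.character(as.Date("2020-06-10") + grid$rep)
  grid$unrest_index_cm <- rnorm(nrow(grid), mus[grid$treatment], sd)
  grid$cluster_index <- rnorm(nrow(grid), mus[grid$treatment], sd)
  grid$n_frames <- 900L
  grid
}

test_that("mean_ci is exact for constant data and linear in scale", {
  expect_equal(mean_ci(c(5, 5, 5, 5)), c(mean = 5, lower = 5, upper = 5))
  set.seed(30)
  x <- rnorm(10000, 3, 1)
  ci <- mean_ci(x)
  expect_lt(ci[["lower"]], 3); expect_gt(ci[["upper"]], 3)
  expect_equal(mean_ci(2 * x), 2 * ci)
  expect_error(mean_ci(5), class = "hensight_input_error")
})

test_that("compact letters agree with multcomp on a balanced one-way design", {
  skip_if_not_installed("multcomp")
  set.seed(31)
  d <- data.frame(g = factor(rep(c("a", "b", "c", "d"), each = 8)))
  d$y <- rnorm(32) + c(a = 0, b = 0.2, c = 3, d = 3.2)[d$g]
  fit <- aov(y ~ g, d)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  ref <- multcomp::cld(glht)$mcletters$Letters
  p <- summary(glht)$test$pvalues
  sig <- matrix(FALSE, 4, 4)
  pairs <- t(combn(4, 2))
  for (i in seq_len(nrow(pairs)))
    sig[pairs[i, 1], pairs[i, 2]] <- sig[pairs[i, 2], pairs[i, 1]] <- p[i] < 0.05
  ours <- cld_letters(sig)
  # same sharing structure: groups share a letter iff the reference does
  for (i in 1:3) for (j in (i + 1):4) {
    share_ref <- length(intersect(strsplit(ref[i], "")[[1]],
                                  strsplit(ref[j], "")[[1]])) > 0
    share_ours <- length(intersect(strsplit(ours[i], "")[[1]],
                                   strsplit(ours[j], "")[[1]])) > 0
    expect_identical(share_ours, share_ref)
  }
})

test_that("letters never contradict the pairwise decision matrix", {
  set.seed(32)
  for (rep in 1:25) {
    g <- sample(3:6, 1)
    sig <- matrix(FALSE, g, g)
    for (i in seq_len(g - 1)) for (j in (i + 1):g)
      sig[i, j] <- sig[j, i] <- runif(1) < 0.4
    lt <- cld_letters(sig)
    for (i in seq_len(g - 1)) for (j in (i + 1):g) {
      share <- length(intersect(strsplit(lt[i], "")[[1]],
                                strsplit(lt[j], "")[[1]])) > 0
      if (sig[i, j]) expect_false(share)  # significant pairs never share
      else expect_true(share)             # non-significant pairs always share
    }
  }
})

test_that("aggregate_units averages valid frames per recording and joins labels", {
  idx <- tibble::tibble(
    recording_id = rep(c("r1", "r2", "r3"), each = 4),
    treatment = "blue", date = "2020-06-10",
    period = rep(c("morning", "afternoon", "morning"), each = 4),
    frame = rep(0:3, 3), ts_s = rep(0:3, 3),
    cluster_index = c(2, 2, 2, 2, 1, 3, NA, NA, 5, 5, 5, 5),
    unrest_index_cm = c(NA, 1, 1, 1, NA, 2, 2, 2, NA, 3, 3, 3),
    valid = c(rep(TRUE, 4), TRUE, TRUE, FALSE, FALSE, rep(TRUE, 4))
  )
  labels <- tibble::tibble(recording_id = c("r1", "r2"),
                           comfort = factor(c("comfort", "heat"),
                                            levels = c("cold", "comfort", "heat")))
  units <- suppressMessages(aggregate_units(idx, labels))
  expect_equal(nrow(units), 2)  # r3 unlabeled, excluded
  expect_equal(units$cluster_index[units$recording_id == "r1"], 2)
  expect_equal(units$cluster_index[units$recording_id == "r2"], 2)  # valid half only
  expect_equal(units$n_frames[units$recording_id == "r2"], 2)
  expect_equal(units$unrest_index_cm, c(1, 2))
})

test_that("a 5-sigma shifted group gets its own letter; equal groups share", {
  units <- make_units(c(blue = 0, green = 0, red = 5), n_per_cell = 6, sd = 1, seed = 33)
  cmp <- anova_tukey(units, "unrest", "period")
  cells <- cmp$cells
  for (lv in levels(cells$level)) {
    sl <- cells[cells$level == lv, ]
    red <- sl$letters_treatment[sl$treatment == "red"]
    others <- sl$letters_treatment[sl$treatment != "red"]
    expect_false(any(grepl(red, others, fixed = TRUE)))
    expect_true(length(intersect(strsplit(others[1], "")[[1]],
                                 strsplit(others[2], "")[[1]])) > 0)
  }
  expect_lt(cmp$anova$p_value[cmp$anova$term == "treatment"], 0.05)
})

test_that("the comparison table has the period/comfort x treatment layout", {
  units <- make_units(c(blue = 1, green = 2, red = 3), seed = 34)
  cmp <- anova_tukey(units, "cluster", "comfort")
  expect_s3_class(cmp, "hensight_comparison")
  expect_setequal(names(cmp$table), c("level", "blue", "green", "red"))
  expect_equal(nrow(cmp$table), 2)  # only scheduled comfort levels present
  expect_output(print(cmp), "lowercase")
  expect_error(anova_tukey(units[units$treatment == "blue", ], "cluster", "comfort"),
               class = "hensight_input_error")
})

test_that("report writes tables, figures and a reproducible manifest", {
  units <- make_units(c(blue = 1, green = 1.5, red = 4), seed = 35)
  dir <- withr::local_tempdir()
  out <- report(units, dir, config = list(variant = "n_minus_1"), seed = 35)
  files <- basename(out$files)
  expect_true(all(c("units.csv", "manifest.json", "fig_ci_means.png",
                    "fig_daily_means.png", "fig_interaction.png",
                    "table_unrest_by_period.csv", "table_cluster_by_comfort.csv")
                  %in% files))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 35)
  expect_equal(man$n_units, nrow(units))
  # rerun reproduces the CSV outputs byte for byte
  dir2 <- withr::local_tempdir()
  report(units, dir2, config = list(variant = "n_minus_1"), seed = 35)
  for (f in grep("csv$", files, value = TRUE))
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  expect_error(report(units[0, ], dir), class = "hensight_input_error")
})
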