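#' Aggregate per-frame indexes into per-recording observation units
#'
#' The experimental unit of all comparisons is one 15-min recording, not one
#' frame: frames of a recording are strongly autocorrelated and would
#' pseudo-replicate. Each recording's mean cluster and unrest index is
#' computed over its valid frames only, then joined with its thermal-comfort
#' label. Recordings without a comfort label are excluded (reported).
#'
#' @param indexes Tibble with one row per frame: `recording_id`,
#'   `treatment`, `date`, `period`, plus the [index_series()] columns.
#' @param labels Tibble with `recording_id` and `comfort` (from
#'   [label_recordings()]).
#' @return Tibble with one row per recording: `recording_id`, `treatment`,
#'   `date`, `period`, `comfort`, `cluster_index`, `unrest_index_cm`,
#'   `n_frames` (valid frames contributing to the cluster mean).
#' @export
aggregate_units <- function(indexes, labels) {
  units <- indexes |>
    dplyr::group_by(recording_id, treatment, date, period) |>
    dplyr::summarise(
      cluster_index = mean(cluster_index[valid], na.rm = TRUE),
      unrest_index_cm = mean(unrest_index_cm, na.rm = TRUE),
      n_frames = sum(valid),
      .groups = "drop"
    ) |>
    dplyr::left_join(labels[, c("recording_id", "comfort")], by = "recording_id")
  unlabeled <- is.na(units$comfort)
  if (any(unlabeled))
    message(sum(unlabeled), " recording(s) without comfort label excluded")
  units[!unlabeled, ]
}

#' t-based confidence interval of a mean
#'
#' @param values Numeric vector, `n >= 2`.
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(mean, lower, upper)`.
#' @export
mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop_input("mean_ci needs at least 2 values")
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, n - 1) * sd(values) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Compact letter display from a pairwise decision matrix
#'
#' Insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different. Letters are assigned so that the first group
#' carries `a`.
#'
#' @param diff Symmetric logical matrix; `TRUE` marks a significantly
#'   different pair.
#' @return Character vector of letter strings, one per group.
#' @export
cld_letters <- function(diff) {
  g <- nrow(diff)
  cols <- list(rep(TRUE, g))  # letter columns: logical membership vectors
  pairs <- which(diff & upper.tri(diff), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        new1 <- col; new1[i] <- FALSE
        new2 <- col; new2[j] <- FALSE
        cols[[ci]] <- new1
        cols[[length(cols) + 1]] <- new2
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols))
      if (a != b && keep[a] && keep[b] && all(cols[[a]] <= cols[[b]]) &&
          any(cols[[a]] != cols[[b]])) keep[a] <- FALSE
    # drop exact duplicates
    sig <- vapply(cols, function(x) paste(as.integer(x), collapse = ""), character(1))
    keep <- keep & !duplicated(sig)
    cols <- cols[keep]
  }
  # letter 'a' goes to the column containing the first group, and so on
  cols <- cols[order(vapply(cols, function(x) min(which(x)), numeric(1)))]
  vapply(seq_len(g), function(i) {
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
}

# Tukey studentized-range p-values for all pairs of cell means, using the
# harmonic mean of the cell sizes and an externally supplied error variance
tukey_pairs <- function(means, ns, mse, df_err) {
  k <- length(means)
  n_h <- k / sum(1 / ns)
  se <- sqrt(mse / n_h)
  p <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    q <- abs(means[i] - means[j]) / se
    p[i, j] <- p[j, i] <- ptukey(q, k, df_err, lower.tail = FALSE)
  }
  diag(p) <- 1
  p
}

#' Two-way ANOVA with Tukey-lettered comparison table
#'
#' Fits `response ~ treatment * factor_b` on per-recording means, then runs
#' Tukey studentized-range comparisons in both directions: across treatments
#' within each level of `factor_b` (lowercase letters) and across levels of
#' `factor_b` within each treatment (uppercase letters). Groups sharing a
#' letter are not significantly different at `alpha`. Unbalanced cells are
#' handled by the studentized-range procedure on cell means with the
#' harmonic mean of the cell sizes; the error variance and degrees of
#' freedom come from the two-way fit. Cells with fewer than 2 units are
#' omitted from comparisons (reported).
#'
#' @param units Tibble from [aggregate_units()].
#' @param response `"unrest"` or `"cluster"`.
#' @param factor_b `"period"` or `"comfort"`.
#' @param alpha Significance level for the letters (default 0.05).
#' @return A `hensight_comparison` list: `cells` (level, treatment, mean, n,
#'   letters), `table` (wide, formatted), `anova` (term, df, F, p),
#'   `response`, `factor_b`, `alpha`, `omitted`.
#' @export
anova_tukey <- function(units, response = c("unrest", "cluster"),
                        factor_b = c("period", "comfort"), alpha = 0.05) {
  response <- match.arg(response)
  factor_b <- match.arg(factor_b)
  ycol <- c(unrest = "unrest_index_cm", cluster = "cluster_index")[[response]]
  d <- tibble::tibble(
    y = units[[ycol]],
    treatment = factor(units$treatment),
    level = factor(units[[factor_b]])
  )
  d <- d[stats::complete.cases(d), ]
  d$level <- droplevels(d$level)
  d$treatment <- droplevels(d$treatment)
  if (nlevels(d$treatment) < 2 || nlevels(d$level) < 2)
    stop_input("anova_tukey needs at least 2 levels of each factor")
  fit <- aov(y ~ treatment * level, data = d)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  anova_tbl <- tibble::tibble(
    term = terms,
    df = an$Df, statistic = an$`F value`, p_value = an$`Pr(>F)`
  )
  mse <- an$`Mean Sq`[terms == "Residuals"]
  df_err <- an$Df[terms == "Residuals"]
  cells <- d |>
    dplyr::group_by(level, treatment) |>
    dplyr::summarise(mean = mean(y), n = dplyr::n(), .groups = "drop")
  omitted <- cells[cells$n < 2, c("level", "treatment")]
  if (nrow(omitted))
    message(nrow(omitted), " cell(s) with < 2 units omitted from comparisons")
  usable <- cells$n >= 2
  letter_for <- function(sub) {
    # letters for one slice; returns NA letters if < 2 usable cells
    if (nrow(sub) < 2) return(rep("", nrow(sub)))
    p <- tukey_pairs(sub$mean, sub$n, mse, df_err)
    cld_letters(p < alpha)
  }
  cells$letters_treatment <- ""
  cells$letters_level <- ""
  for (lv in levels(cells$level)) {
    idx <- which(cells$level == lv & usable)
    cells$letters_treatment[idx] <- letter_for(cells[idx, ])
  }
  for (tr in levels(cells$treatment)) {
    idx <- which(cells$treatment == tr & usable)
    cells$letters_level[idx] <- toupper(letter_for(cells[idx, ]))
  }
  wide <- cells |>
    dplyr::mutate(cell = sprintf("%.3f %s%s", mean, letters_treatment, letters_level)) |>
    dplyr::select(level, treatment, cell) |>
    tidyr::pivot_wider(names_from = treatment, values_from = cell)
  structure(list(cells = cells, table = wide, anova = anova_tbl,
                 response = response, factor_b = factor_b, alpha = alpha,
                 omitted = omitted),
            class = "hensight_comparison")
}

#' @export
print.hensight_comparison <- function(x, ...) {
  cat("Tukey comparison of", x$response, "index by treatment x", x$factor_b,
      sprintf("(alpha = %g)\n", x$alpha))
  cat("lowercase: across treatments within a level;",
      "uppercase: across levels within a treatment\n\n")
  print(x$table)
  invisible(x)
}

#' Write a report bundle
#'
#' Writes the per-recording units, the Tukey comparison tables for both
#' responses by period and by comfort class, three figures (confidence
#' intervals of the treatment means, daily mean curves by period, and
#' comfort x treatment interaction profiles) and a JSON run manifest
#' recording the package version, configuration and seed. Outputs are plain
#' CSV/PNG/JSON and contain no wall-clock state, so a rerun with the same
#' inputs reproduces them byte for byte.
#'
#' @param units Tibble from [aggregate_units()]; must be nonempty.
#' @param out_dir Output directory (created if absent).
#' @param config List echoed into the manifest (variant, thresholds, ...).
#' @param seed Seed echoed into the manifest.
#' @param alpha Significance level for the tables.
#' @return Invisibly, a list with the comparison objects and file paths.
#' @export
report <- function(units, out_dir, config = list(), seed = NULL, alpha = 0.05) {
  if (!nrow(units)) stop_input("no observation units to report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(units, file.path(out_dir, "units.csv"))
  comparisons <- list()
  for (resp in c("unrest", "cluster")) for (fb in c("period", "comfort")) {
    key <- paste(resp, fb, sep = "_by_")
    cmp <- tryCatch(anova_tukey(units, resp, fb, alpha),
                    hensight_input_error = function(e) NULL)
    if (is.null(cmp)) next
    comparisons[[key]] <- cmp
    readr::write_csv(cmp$table, file.path(out_dir, paste0("table_", key, ".csv")))
  }
  long <- units |>
    tidyr::pivot_longer(c(unrest_index_cm, cluster_index),
                        names_to = "response", values_to = "value")
  ci <- long |>
    dplyr::group_by(response, treatment) |>
    dplyr::summarise(m = mean(value, na.rm = TRUE),
                     lo = mean_ci(value)[["lower"]],
                     hi = mean_ci(value)[["upper"]], .groups = "drop")
  p1 <- ggplot2::ggplot(ci, ggplot2::aes(treatment, m, colour = treatment)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi), width = 0.2) +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(y = "mean (95% CI)", x = NULL) +
    ggplot2::theme_bw() + ggplot2::theme(legend.position = "none")
  ggplot2::ggsave(file.path(out_dir, "fig_ci_means.png"), p1,
                  width = 7, height = 3.5, dpi = 120)
  daily <- long |>
    dplyr::group_by(response, treatment, date, period) |>
    dplyr::summarise(value = mean(value, na.rm = TRUE), .groups = "drop")
  p2 <- ggplot2::ggplot(daily, ggplot2::aes(as.Date(date), value, colour = treatment,
                                            linetype = period)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = "day", y = "daily mean") +
    ggplot2::theme_bw()
  ggplot2::ggsave(file.path(out_dir, "fig_daily_means.png"), p2,
                  width = 7, height = 3.5, dpi = 120)
  inter <- long |>
    dplyr::group_by(response, treatment, comfort) |>
    dplyr::summarise(value = mean(value, na.rm = TRUE), .groups = "drop")
  p3 <- ggplot2::ggplot(inter, ggplot2::aes(comfort, value, colour = treatment,
                                            group = treatment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = "thermal comfort class", y = "mean index") +
    ggplot2::theme_bw()
  ggplot2::ggsave(file.path(out_dir, "fig_interaction.png"), p3,
                  width = 7, height = 3.5, dpi = 120)
  manifest <- list(
    package = "hensight",
    version = as.character(utils::packageVersion("hensight")),
    seed = seed,
    alpha = alpha,
    config = config,
    config_hash = rlang::hash(config),
    n_units = nrow(units)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(comparisons = comparisons, out_dir = out_dir,
                 files = list.files(out_dir, full.names = TRUE)))
}
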