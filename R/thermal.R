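#' Temperature-humidity index (THI)
#'
#' `THI = 0.8 * T + RH * (T - 14.3) / 100 + 46.3`, with `T` the dry-bulb
#' temperature in degrees Celsius and `RH` the relative humidity in percent.
#' THI is strictly increasing in `T` (slope `0.8 + RH/100`); it increases
#' with `RH` above 14.3 C and decreases with `RH` below it. Vectorized.
#'
#' @param temp_c Dry-bulb temperature, C; must lie in (-20, 60).
#' @param rh_pct Relative humidity, percent, in `[0, 100]`.
#' @return THI value(s).
#' @export
thi <- function(temp_c, rh_pct) {
  if (any(!is.finite(temp_c)) || any(temp_c <= -20 | temp_c >= 60))
    stop_input("temp_c must lie in (-20, 60) C")
  if (any(!is.finite(rh_pct)) || any(rh_pct < 0 | rh_pct > 100))
    stop_input("rh_pct must lie in [0, 100]")
  0.8 * temp_c + rh_pct * (temp_c - 14.3) / 100 + 46.3
}

#' Thermal-comfort thresholds for laying hens
#'
#' Literature limits of the thermoneutral zone: THI below 59 (or, under the
#' joint rule, air temperature below 15 C) indicates cold stress; THI above
#' 78 (or temperature above 28 C) indicates heat stress.
#'
#' @param thi_cold,thi_heat THI limits (defaults 59 and 78).
#' @param t_cold,t_heat Temperature limits in C (defaults 15 and 28), used
#'   only by the `thi_or_temp` rule of [classify_comfort()].
#' @return A `comfort_thresholds` object.
#' @export
comfort_thresholds <- function(thi_cold = 59, thi_heat = 78, t_cold = 15, t_heat = 28) {
  if (thi_cold >= thi_heat) stop_config("thi_cold must be < thi_heat")
  if (t_cold >= t_heat) stop_config("t_cold must be < t_heat")
  structure(list(thi_cold = thi_cold, thi_heat = thi_heat,
                 t_cold = t_cold, t_heat = t_heat), class = "comfort_thresholds")
}

#' Classify thermal comfort
#'
#' Labels each observation `"cold"`, `"comfort"` or `"heat"`. Thresholds are
#' strict inequalities ("above" / "below"), so values exactly at a limit are
#' comfort. The default `thi_only` rule uses THI alone; `thi_or_temp`
#' additionally triggers heat at `T > t_heat` and cold at `T < t_cold`
#' (heat checked first). Vectorized; exhaustive and exclusive for finite
#' inputs.
#'
#' @param thi_value THI value(s).
#' @param t_mean Mean air temperature(s), C; required for `thi_or_temp`.
#' @param thresholds A [comfort_thresholds()].
#' @param rule `"thi_only"` (default) or `"thi_or_temp"`.
#' @return Factor with levels `cold`, `comfort`, `heat`.
#' @export
classify_comfort <- function(thi_value, t_mean = NULL,
                             thresholds = comfort_thresholds(),
                             rule = c("thi_only", "thi_or_temp")) {
  rule <- match.arg(rule)
  stopifnot(inherits(thresholds, "comfort_thresholds"))
  heat <- thi_value > thresholds$thi_heat
  cold <- thi_value < thresholds$thi_cold
  if (rule == "thi_or_temp") {
    if (is.null(t_mean)) stop_input("rule thi_or_temp requires t_mean")
    heat <- heat | t_mean > thresholds$t_heat
    cold <- (cold | t_mean < thresholds$t_cold) & !heat
  }
  out <- rep("comfort", length(thi_value))
  out[cold] <- "cold"
  out[heat] <- "heat"
  factor(out, levels = c("cold", "comfort", "heat"))
}

#' Hourly means of a thermal log
#'
#' Groups records by clock hour and returns the mean temperature and
#' humidity plus the hour's THI, computed from the hourly means (not as the
#' mean of per-record THI -- the difference is second order, but one
#' convention has to be fixed). Hours with no records are absent from the
#' output, not zero-filled.
#'
#' @param records Tibble with `timestamp` (POSIXct, sorted), `temp_c`,
#'   `rh_pct`.
#' @return Tibble with `hour` (POSIXct), `n`, `temp_c`, `rh_pct`, `thi`.
#' @export
hourly_means <- function(records) {
  if (is.unsorted(as.numeric(records$timestamp)))
    stop_input("thermal records must be sorted by timestamp")
  hr <- as.POSIXct(trunc(records$timestamp, units = "hours"))
  out <- records |>
    dplyr::mutate(hour = hr) |>
    dplyr::group_by(hour) |>
    dplyr::summarise(n = dplyr::n(), temp_c = mean(temp_c), rh_pct = mean(rh_pct),
                     .groups = "drop")
  out$thi <- thi(out$temp_c, out$rh_pct)
  out
}

#' Label recording windows by thermal-comfort class
#'
#' Each recording window (e.g. a 15-min video) is labeled by the comfort
#' class of the mean THI over the clock hours it overlaps. Windows with no
#' thermal coverage are labeled `NA` and reported, so they can be excluded
#' downstream rather than silently dropped.
#'
#' @param windows Tibble with `recording_id`, `start`, `end` (POSIXct).
#' @param hourly Hourly table from [hourly_means()].
#' @param thresholds A [comfort_thresholds()].
#' @param rule Classification rule, see [classify_comfort()].
#' @return `windows` with added `thi_mean`, `t_mean` and `comfort` columns.
#' @export
label_recordings <- function(windows, hourly, thresholds = comfort_thresholds(),
                             rule = "thi_only") {
  stats <- purrr::map(seq_len(nrow(windows)), function(i) {
    ov <- hourly$hour < windows$end[i] & (hourly$hour + 3600) > windows$start[i]
    if (!any(ov)) return(c(NA_real_, NA_real_))
    c(mean(hourly$thi[ov]), mean(hourly$temp_c[ov]))
  })
  windows$thi_mean <- vapply(stats, `[`, numeric(1), 1)
  windows$t_mean <- vapply(stats, `[`, numeric(1), 2)
  covered <- !is.na(windows$thi_mean)
  comfort <- factor(rep(NA_character_, nrow(windows)), levels = c("cold", "comfort", "heat"))
  if (any(covered))
    comfort[covered] <- classify_comfort(windows$thi_mean[covered],
                                         windows$t_mean[covered], thresholds, rule)
  windows$comfort <- comfort
  if (any(!covered))
    message(sum(!covered), " recording window(s) without thermal coverage labeled NA")
  windows
}

#' Read a datalogger CSV
#'
#' Expects columns `timestamp` (ISO-8601), `temp_c`, `rh_pct`; nominally a
#' 5-min cadence but tolerant of gaps.
#'
#' @param path CSV path.
#' @return Tibble with POSIXct `timestamp` (UTC), `temp_c`, `rh_pct`.
#' @export
read_thermal_log <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("timestamp", "temp_c", "rh_pct") %in% names(out)))
    stop_input("thermal log must have columns timestamp, temp_c, rh_pct")
  out$timestamp <- as.POSIXct(out$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%d %H:%M:%S"))
  out
}
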