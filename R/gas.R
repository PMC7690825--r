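#' Collection exclusion windows
#'
#' Parse clock-time windows (e.g. the twice-daily feces/urine collection
#' periods, when chamber doors are open and gas readings do not reflect the
#' animal) into minute-of-day intervals for exclusion from the daily
#' integration.
#'
#' @param windows character vector of `"HH:MM-HH:MM"` windows, all within one
#'   clock day and non-overlapping. The default is the standard collection
#'   schedule 08:00-08:30 and 15:00-15:30.
#' @return data.frame with `start_min`, `end_min` (minutes since midnight,
#'   end exclusive), sorted.
#' @examples
#' exclusion_windows()
#' @export
exclusion_windows <- function(windows = c("08:00-08:30", "15:00-15:30")) {
  if (length(windows) == 0)
    return(data.frame(start_min = numeric(0), end_min = numeric(0)))
  parse_hm <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    p[1] * 60 + p[2]
  }
  parts <- strsplit(windows, "-", fixed = TRUE)
  out <- data.frame(
    start_min = vapply(parts, function(p) parse_hm(p[1]), numeric(1)),
    end_min   = vapply(parts, function(p) parse_hm(p[2]), numeric(1))
  )
  out <- out[order(out$start_min), , drop = FALSE]
  if (any(out$end_min <= out$start_min) || any(out$end_min > 1440))
    stop("exclusion windows must lie within one clock day")
  if (nrow(out) > 1 && any(out$start_min[-1] < out$end_min[-nrow(out)]))
    stop("exclusion windows overlap")
  out
}

# internal: validate a chamber log and return its sampling interval (min)
validate_chamber_series <- function(series) {
  need <- c("timestamp", "o2_in_pct", "o2_out_pct", "co2_in_pct",
            "co2_out_pct", "ch4_in_pct", "ch4_out_pct", "flow_L_min")
  missing <- setdiff(need, names(series))
  if (length(missing))
    stop("chamber series is missing columns: ", paste(missing, collapse = ", "))
  ts <- as.numeric(series$timestamp)
  if (is.unsorted(ts, strictly = TRUE))
    stop("chamber timestamps must be strictly increasing")
  d <- diff(ts)
  interval <- d[1] / 60
  if (any(abs(d - d[1]) > 1e-6))
    stop("chamber sampling interval is not constant")
  conc <- as.matrix(series[grep("_pct$", names(series))])
  if (any(!is.finite(conc)) || any(conc < 0) || any(conc > 100))
    stop("gas concentrations must be fractions in [0, 100] percent")
  if (any(series$flow_L_min <= 0)) stop("airflow must be positive")
  interval
}

#' Daily gas exchange from a chamber log
#'
#' Integrate an open-circuit respiration-chamber log into daily gas volumes.
#' O2 consumption is airflow times the inlet-minus-outlet concentration
#' differential; CO2 and CH4 production use outlet minus inlet. Samples
#' falling in the collection exclusion windows are dropped and the retained
#' integral is rescaled by `1440 / (1440 - minutes_excluded)` to a 24-h
#' equivalent. Only complete clock days (00:00-24:00) are integrated;
#' partial leading or trailing days are ignored.
#'
#' A slightly negative daily volume (analyzer noise around a zero
#' differential) is clipped to zero with a warning when it is within 0.5% of
#' the mean daily magnitude of that gas; a larger negative volume is a QC
#' error.
#'
#' @param series chamber log: data.frame with `timestamp` (POSIXct),
#'   `o2_in_pct`, `o2_out_pct`, `co2_in_pct`, `co2_out_pct`, `ch4_in_pct`,
#'   `ch4_out_pct` (volume percent), `flow_L_min`.
#' @param windows exclusion windows from [exclusion_windows()].
#' @param max_missing_frac maximum tolerated fraction of missing samples in a
#'   day before a coverage error is raised.
#' @param neg_tol relative tolerance for negative daily volumes.
#' @return data.frame with one row per complete day: `day` (Date),
#'   `o2_L`, `co2_L`, `ch4_L` (L/24 h), `rq`, `minutes_excluded`.
#' @examples
#' log <- gas_log_from_truth(data.frame(day = 1, o2_L = 1800, co2_L = 1800,
#'                                      ch4_L = 0, urine_n_g = 0))
#' compute_gas_volumes(log)
#' @export
compute_gas_volumes <- function(series, windows = exclusion_windows(),
                                max_missing_frac = 0.05, neg_tol = 0.005) {
  interval <- validate_chamber_series(series)
  lt <- as.POSIXlt(series$timestamp, tz = "UTC")
  minute <- lt$hour * 60 + lt$min
  day <- as.Date(series$timestamp, tz = "UTC")
  per_day <- 1440 / interval

  excluded <- rep(FALSE, nrow(series))
  for (i in seq_len(nrow(windows)))
    excluded <- excluded | (minute >= windows$start_min[i] & minute < windows$end_min[i])
  win_minutes <- sum(windows$end_min - windows$start_min)

  days <- sort(unique(day))
  counts <- table(day)
  # interior days must be (nearly) complete; boundary days may be partial
  interior <- days[days > min(days) & days < max(days)]
  bad <- interior[counts[as.character(interior)] < per_day * (1 - max_missing_frac)]
  if (length(bad))
    stop("coverage error: day ", paste(bad, collapse = ", "),
         " is missing more than ", 100 * max_missing_frac, "% of samples")
  use_days <- days[counts[as.character(days)] >= per_day * (1 - max_missing_frac)]
  if (length(use_days) == 0)
    stop("coverage error: no complete day of samples in the chamber log")

  integrate_gas <- function(keep, inlet, outlet, sign) {
    sum(series$flow_L_min[keep] * sign *
          (series[[outlet]][keep] - series[[inlet]][keep]) / 100 * interval)
  }
  res <- lapply(use_days, function(d) {
    keep <- day == d & !excluded
    n_missing <- per_day - sum(day == d)
    minutes_out <- win_minutes + n_missing * interval
    scale <- 1440 / (1440 - minutes_out)
    data.frame(
      day = d,
      o2_L  = scale * integrate_gas(keep, "o2_out_pct", "o2_in_pct", 1),
      co2_L = scale * integrate_gas(keep, "co2_in_pct", "co2_out_pct", 1),
      ch4_L = scale * integrate_gas(keep, "ch4_in_pct", "ch4_out_pct", 1),
      minutes_excluded = minutes_out
    )
  })
  out <- do.call(rbind, res)

  for (gas in c("o2_L", "co2_L", "ch4_L")) {
    v <- out[[gas]]
    tol <- neg_tol * mean(abs(v))
    if (any(v < -tol))
      stop("QC error: negative daily ", sub("_L", "", gas), " volume beyond tolerance")
    if (any(v < 0)) {
      warning("clipping slightly negative ", sub("_L", "", gas), " volume(s) to zero")
      out[[gas]] <- pmax(v, 0)
    }
  }
  out$rq <- ifelse(out$o2_L > 0, out$co2_L / out$o2_L, NA_real_)
  out[c("day", "o2_L", "co2_L", "ch4_L", "rq", "minutes_excluded")]
}

#' Fasting-night gas volumes and 24-h extrapolation
#'
#' Extract the 22:00-06:00 fasting window (the last such night covered by the
#' log), sum its gas volumes, and extrapolate linearly to 24 h (factor 3 for
#' the 8-h window).
#'
#' @param series chamber log as in [compute_gas_volumes()].
#' @param start,end clock times (`"HH:MM"`) bounding the window; a window
#'   whose end precedes its start spans midnight and is handled as one
#'   contiguous block.
#' @return list with `o2_8h`, `co2_8h`, `ch4_8h` (L over the window),
#'   `factor` (24 h / window length), `o2_24h`, `co2_24h`, `ch4_24h`, `rq`.
#' @examples
#' truth <- data.frame(day = 1:2, o2_L = c(1800, 900), co2_L = c(1890, 720),
#'                     ch4_L = c(10, 2), urine_n_g = c(30, 10))
#' log <- gas_log_from_truth(truth, fast_days = 2)
#' fasting_window_volumes(log)
#' @export
fasting_window_volumes <- function(series, start = "22:00", end = "06:00") {
  interval <- validate_chamber_series(series)
  parse_hm <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]]); p[1] * 60 + p[2]
  }
  s_min <- parse_hm(start); e_min <- parse_hm(end)
  span <- if (e_min > s_min) e_min - s_min else 1440 - s_min + e_min
  n_expected <- span / interval

  lt <- as.POSIXlt(series$timestamp, tz = "UTC")
  minute <- lt$hour * 60 + lt$min
  in_window <- if (e_min > s_min) minute >= s_min & minute < e_min
               else minute >= s_min | minute < e_min
  # last contiguous block of in-window samples
  idx <- which(in_window)
  if (length(idx) == 0) stop("coverage error: fasting window not present in log")
  brk <- c(which(diff(idx) > 1), length(idx))
  last_end <- idx[brk[length(brk)]]
  last_start <- idx[if (length(brk) > 1) brk[length(brk) - 1] + 1 else 1]
  block <- last_start:last_end
  if (length(block) < n_expected)
    stop("coverage error: fasting window ", start, "-", end,
         " is incompletely covered (", length(block), "/", n_expected, " samples)")

  vol <- function(inlet, outlet, sign)
    sum(series$flow_L_min[block] * sign *
          (series[[outlet]][block] - series[[inlet]][block]) / 100 * interval)
  o2  <- vol("o2_out_pct", "o2_in_pct", 1)
  co2 <- vol("co2_in_pct", "co2_out_pct", 1)
  ch4 <- vol("ch4_in_pct", "ch4_out_pct", 1)
  factor <- 1440 / span
  list(o2_8h = o2, co2_8h = co2, ch4_8h = ch4, factor = factor,
       o2_24h = factor * o2, co2_24h = factor * co2, ch4_24h = factor * ch4,
       rq = if (o2 > 0) co2 / o2 else NA_real_)
}
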