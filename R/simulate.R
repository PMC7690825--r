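# internal: run code with a locally seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Diet specification
#'
#' Chemical composition of a complete diet, as-fed basis: dry matter
#' fraction, gross energy (MJ/kg) and crude protein fraction.
#'
#' @param dm_fraction dry matter as fraction of as-fed weight, in (0, 1].
#' @param ge_MJ_per_kg gross energy, MJ per kg as-fed.
#' @param cp_fraction crude protein fraction of as-fed weight.
#' @return list of class `diet_spec`.
#' @examples
#' diet_spec()  # corn-soybean grower diet, 25 kg stage
#' @export
diet_spec <- function(dm_fraction = 0.895, ge_MJ_per_kg = 16.38,
                      cp_fraction = 0.1778) {
  stopifnot(dm_fraction > 0, dm_fraction <= 1,
            cp_fraction > 0, cp_fraction <= 1, ge_MJ_per_kg > 0)
  structure(list(dm_fraction = dm_fraction, ge_MJ_per_kg = ge_MJ_per_kg,
                 cp_fraction = cp_fraction), class = "diet_spec")
}

#' Respiration-chamber trial design
#'
#' The design of one growth-stage trial: the set of chamber temperatures, the
#' number of successive replicates per temperature, the entry-bodyweight
#' distribution, the diet, and the chamber measurement regime (balance days,
#' gas sampling interval, airflow).
#'
#' `trial_design_25kg()` and `trial_design_65kg()` return the two standard
#' designs: six temperatures (18, 21, 23, 27, 29, 32 degC) with six
#' replicates at about 25 kg, and four temperatures (18, 23, 27, 32 degC)
#' with six replicates at about 65 kg.
#'
#' @param stage_label label for the growth stage.
#' @param temperatures_C strictly increasing ambient temperatures, degC.
#' @param replicates_per_temperature animals per temperature (>= 1).
#' @param initial_bw_mean_kg,initial_bw_sd_kg chamber-entry bodyweight
#'   distribution, kg.
#' @param diet a [diet_spec()].
#' @param n_balance_days fed balance days in the chamber (default 5),
#'   followed by one fasting day.
#' @param sampling_interval_min gas sampling interval; must divide 1440.
#' @param airflow_L_per_min chamber airflow.
#' @return list of class `trial_design`.
#' @examples
#' trial_design_25kg()
#' @export
trial_design <- function(stage_label, temperatures_C,
                         replicates_per_temperature = 6,
                         initial_bw_mean_kg, initial_bw_sd_kg,
                         diet = diet_spec(), n_balance_days = 5,
                         sampling_interval_min = 5, airflow_L_per_min = 250) {
  if (length(temperatures_C) == 0) stop("design error: empty temperature list")
  if (is.unsorted(temperatures_C, strictly = TRUE))
    stop("design error: temperatures must be strictly increasing")
  if (replicates_per_temperature < 1)
    stop("design error: replicates per temperature must be >= 1")
  if (1440 %% sampling_interval_min != 0)
    stop("design error: sampling interval must divide 1440 minutes")
  stopifnot(initial_bw_mean_kg > 0, initial_bw_sd_kg >= 0,
            airflow_L_per_min > 0, n_balance_days >= 1,
            inherits(diet, "diet_spec"))
  structure(list(
    stage_label = stage_label, temperatures_C = temperatures_C,
    replicates_per_temperature = replicates_per_temperature,
    initial_bw_mean_kg = initial_bw_mean_kg,
    initial_bw_sd_kg = initial_bw_sd_kg, diet = diet,
    n_balance_days = n_balance_days,
    sampling_interval_min = sampling_interval_min,
    airflow_L_per_min = airflow_L_per_min
  ), class = "trial_design")
}

#' @rdname trial_design
#' @export
trial_design_25kg <- function() {
  trial_design("25kg", c(18, 21, 23, 27, 29, 32), 6, 26.4, 1.9,
               diet_spec(0.895, 16.38, 0.1778))
}

#' @rdname trial_design
#' @export
trial_design_65kg <- function() {
  trial_design("65kg", c(18, 23, 27, 32), 6, 64.2, 3.1,
               diet_spec(0.896, 16.67, 0.1620))
}

#' Generating parameters for the synthetic trial
#'
#' The ground-truth model behind the simulator. Feed intake follows the
#' bodyweight-by-temperature response surface (see
#' [pig_surface_coefficients()]); digestibility, urinary and methane energy
#' losses, and the nitrogen partition are drawn per animal around typical
#' grower-pig values; fed total heat production (per kg BW^0.6) rises
#' linearly with metabolizable energy intake; fasting heat production and
#' the fed/fasting respiratory quotients are drawn per animal. Daily gas
#' volumes are then derived so that the Brouwer combination of the true
#' volumes and urinary nitrogen reproduces the true heat production exactly
#' (closure by construction).
#'
#' @param noise_scale multiplier applied to every noise SD; `0` gives a
#'   deterministic, noise-free trial in which the analysis pipeline must
#'   reproduce the ground truth to numerical precision.
#' @param ... named overrides of individual parameters.
#' @return list of class `trial_truth_params`.
#' @examples
#' trial_truth_params(noise_scale = 0)$intake_noise_sd
#' @export
trial_truth_params <- function(noise_scale = 1, ...) {
  p <- list(
    intake_coeffs = pig_surface_coefficients()$vfi,
    intake_noise_sd = 0.12,     # animal-level lognormal SD on intake
    intake_day_sd = 0.03,       # day-to-day lognormal SD on intake
    de_ge_mean = 0.855, de_ge_sd = 0.012,
    urine_e_frac_mean = 0.011, urine_e_frac_sd = 0.002,
    ch4_e_frac_mean = 0.004, ch4_e_frac_sd = 0.0008,
    fecal_n_frac_mean = 0.155, fecal_n_frac_sd = 0.015,
    urine_n_frac_mean = 0.125, urine_n_frac_sd = 0.020,
    thp_intercept = 290, thp_slope = 0.31, thp_sd = 100,   # kJ/kg BW^0.6/d
    fhp_mean = 700, fhp_sd = 90,                           # kJ/kg BW^0.6/d
    rq_fed_mean = 1.07, rq_fed_sd = 0.02,
    rq_fast_mean = 0.80, rq_fast_sd = 0.015,
    fast_urine_n_frac = 0.8,    # fasting urinary N as fraction of fed daily N
    adg_kg_d = 0.9,
    analyzer_noise_pp = c(o2 = 0.003, co2 = 0.002, ch4 = 0.0002),
    window_factor = 0.5         # damping of differentials while doors open
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown truth parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  sds <- c("intake_noise_sd", "intake_day_sd", "de_ge_sd", "urine_e_frac_sd",
           "ch4_e_frac_sd", "fecal_n_frac_sd", "urine_n_frac_sd", "thp_sd",
           "fhp_sd", "rq_fed_sd", "rq_fast_sd")
  for (s in sds) p[[s]] <- p[[s]] * noise_scale
  p$analyzer_noise_pp <- p$analyzer_noise_pp * noise_scale
  if (any(unlist(p[sds]) < 0)) stop("noise SDs must be nonnegative")
  class(p) <- "trial_truth_params"
  p
}

#' Sample a daily voluntary feed intake
#'
#' The mean response is the quadratic bodyweight-by-temperature surface
#' evaluated at `BW^0.6` and `T`; multiplicative log-normal noise (mean-one,
#' i.e. with the -sd^2/2 correction) is applied on top and the result is
#' truncated at zero from below.
#'
#' @param bw_kg bodyweight (kg, positive).
#' @param temp_C ambient temperature (degC).
#' @param coeffs named coefficients `a`..`f` of the intake surface.
#' @param noise_sd log-scale SD of the multiplicative noise.
#' @return as-fed intake, kg/d.
#' @examples
#' sample_intake(28.7, 18, noise_sd = 0)   # about 1.31 kg/d
#' @export
sample_intake <- function(bw_kg, temp_C, coeffs = pig_surface_coefficients()$vfi,
                          noise_sd = 0) {
  mu <- evaluate_surface(coeffs, bw_kg, temp_C)
  noise <- if (noise_sd > 0)
    exp(stats::rnorm(length(mu), -noise_sd^2 / 2, noise_sd)) else 1
  pmax(mu * noise, 0)
}

#' Generate a chamber gas log from true daily volumes
#'
#' The generative inverse of [compute_gas_volumes()]: given true daily gas
#' volumes, emit the concentration/flow log an open-circuit chamber analyzer
#' would record at a fixed sampling interval, with each day's exchange spread
#' uniformly over its 1440 minutes. Inlet concentrations are held at ambient
#' baselines; outlet concentrations carry the implied differential. During
#' the collection windows (doors open) the differential is damped by
#' `window_factor`; those samples are flagged in `collection_window` and are
#' the ones the analysis excludes. Optional additive Gaussian analyzer noise
#' (in percentage points, per gas) is applied to the outlet readings.
#'
#' Days listed in `fast_days` carry no collection disturbance and, for the
#' final fasting day, the log is extended to 06:00 of the following morning
#' so the 22:00-06:00 fasting window is fully covered.
#'
#' @param daily data.frame with columns `day` (integer), `o2_L`, `co2_L`,
#'   `ch4_L` (true daily volumes, L).
#' @param airflow_L_per_min chamber airflow.
#' @param interval_min sampling interval; must divide 1440.
#' @param fast_days integer vector of fasting day indices (may be empty).
#' @param noise_pp named vector `c(o2=, co2=, ch4=)` of additive analyzer
#'   noise SDs in percentage points.
#' @param window_factor damping of the differential during collection
#'   windows.
#' @param windows collection windows, as [exclusion_windows()].
#' @param baseline_pct named inlet baselines, volume percent.
#' @param start_date first day's date (arbitrary bookkeeping origin).
#' @param seed optional integer seed (local to this call).
#' @return chamber log data.frame as consumed by [compute_gas_volumes()],
#'   with an extra logical `collection_window` column.
#' @examples
#' log <- gas_log_from_truth(data.frame(day = 1, o2_L = 1800, co2_L = 1890,
#'                                      ch4_L = 5))
#' head(log)
#' @export
gas_log_from_truth <- function(daily, airflow_L_per_min = 250, interval_min = 5,
                               fast_days = integer(0),
                               noise_pp = c(o2 = 0, co2 = 0, ch4 = 0),
                               window_factor = 1,
                               windows = exclusion_windows(),
                               baseline_pct = c(o2 = 20.95, co2 = 0.04, ch4 = 0),
                               start_date = as.Date("2020-01-01"),
                               seed = NULL) {
  stopifnot(all(c("day", "o2_L", "co2_L", "ch4_L") %in% names(daily)),
            1440 %% interval_min == 0, airflow_L_per_min > 0)
  with_seed(seed, {
    per_day <- 1440 / interval_min
    rows <- list()
    ranges <- list(o2 = c(19.5, 21.0), co2 = c(0, 1), ch4 = c(0, 0.1))
    for (i in seq_len(nrow(daily))) {
      d <- daily$day[i]
      is_fast <- d %in% fast_days
      extend <- is_fast && d == max(daily$day)
      minutes <- seq(0, 1440 - interval_min, by = interval_min)
      if (extend) minutes <- c(minutes, 1440 + seq(0, 360 - interval_min, by = interval_min))
      # per-minute differential implied by the daily volume
      diff_pp <- c(o2 = daily$o2_L[i], co2 = daily$co2_L[i], ch4 = daily$ch4_L[i]) /
        (airflow_L_per_min * 1440) * 100
      out_peak <- c(o2 = baseline_pct[["o2"]] - diff_pp[["o2"]],
                    co2 = baseline_pct[["co2"]] + diff_pp[["co2"]],
                    ch4 = baseline_pct[["ch4"]] + diff_pp[["ch4"]])
      for (g in c("o2", "co2", "ch4")) {
        if (out_peak[[g]] < ranges[[g]][1] || out_peak[[g]] > ranges[[g]][2])
          stop("range error: implied outlet ", toupper(g),
               " concentration outside the analyzer range")
      }
      ts <- as.POSIXct(start_date, tz = "UTC") + (d - 1) * 86400 + minutes * 60
      min_of_day <- minutes %% 1440
      in_win <- rep(FALSE, length(minutes))
      if (!is_fast) {
        for (w in seq_len(nrow(windows)))
          in_win <- in_win | (min_of_day >= windows$start_min[w] &
                                min_of_day < windows$end_min[w])
      }
      damp <- ifelse(in_win, window_factor, 1)
      n <- length(minutes)
      noise <- function(g) if (noise_pp[[g]] > 0)
        stats::rnorm(n, 0, noise_pp[[g]]) else 0
      rows[[i]] <- data.frame(
        timestamp = ts,
        o2_in_pct = rep(baseline_pct[["o2"]], n),
        o2_out_pct = baseline_pct[["o2"]] - damp * diff_pp[["o2"]] + noise("o2"),
        co2_in_pct = rep(baseline_pct[["co2"]], n),
        co2_out_pct = baseline_pct[["co2"]] + damp * diff_pp[["co2"]] + noise("co2"),
        ch4_in_pct = rep(baseline_pct[["ch4"]], n),
        ch4_out_pct = baseline_pct[["ch4"]] + damp * diff_pp[["ch4"]] + noise("ch4"),
        flow_L_min = airflow_L_per_min,
        collection_window = in_win
      )
    }
    out <- do.call(rbind, rows)
    out$o2_out_pct <- pmin(pmax(out$o2_out_pct, 0), 100)
    out$co2_out_pct <- pmin(pmax(out$co2_out_pct, 0), 100)
    out$ch4_out_pct <- pmin(pmax(out$ch4_out_pct, 0), 100)
    out
  })
}

# internal: truncated-at-bounds normal draw (simple clamp; SDs are small
# relative to the physiological range so the distortion is negligible)
rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a complete respiration-chamber trial
#'
#' Generates, for every animal of a [trial_design()], the balance-period
#' records a real trial would produce -- a chamber gas log at the design's
#' sampling interval covering the fed balance days plus one fasting day (with
#' the 22:00-06:00 fasting night fully logged), a twice-daily collection
#' table (feed, feces, urine, their energy and nitrogen contents), and the
#' animal roster -- together with the complete ground truth used to generate
#' them. Deterministic given `seed`.
#'
#' @param design a [trial_design()].
#' @param truth_params a [trial_truth_params()] bundle.
#' @param seed integer seed.
#' @return list of class `calorimetry_trial` with elements `design`,
#'   `truth_params`, `animals` (roster incl. bodyweights and fasting urinary
#'   N), `collection` (per animal-day), `chambers` (named list of chamber
#'   logs), and `truth` (list: `animal_day` records, `ledger` of true
#'   per-animal energy-balance values, `coefficients` of the generating
#'   intake surface).
#' @examples
#' tr <- simulate_trial(trial_design("toy", c(18, 32), 2, 30, 1), seed = 1)
#' tr$animals
#' @export
simulate_trial <- function(design, truth_params = trial_truth_params(), seed = 1) {
  stopifnot(inherits(design, "trial_design"),
            inherits(truth_params, "trial_truth_params"))
  p <- truth_params
  k <- calorimetry_constants()
  with_seed(seed, {
    temps <- rep(design$temperatures_C, each = design$replicates_per_temperature)
    n_animal <- length(temps)
    ids <- sprintf("%s_p%02d", design$stage_label, seq_len(n_animal))
    n_days <- design$n_balance_days
    fast_day <- n_days + 1

    entry_bw <- rnorm_clamped(n_animal, design$initial_bw_mean_kg,
                              design$initial_bw_sd_kg, lo = 1)
    exit_bw <- entry_bw + p$adg_kg_d * (n_days + 1)
    avg_bw <- (entry_bw + exit_bw) / 2
    mbw <- metabolic_bw(avg_bw, k$metabolic_exponent)

    ge_kJ_per_kg <- design$diet$ge_MJ_per_kg * 1000
    n_per_kg_feed <- design$diet$cp_fraction / k$n_to_protein * 1000  # g N/kg feed

    animals <- data.frame(
      animal = ids, stage = design$stage_label, temp_C = temps,
      chamber = match(temps, design$temperatures_C),
      entry_bw_kg = entry_bw, exit_bw_kg = exit_bw, avg_bw_kg = avg_bw,
      fast_urine_n_g = NA_real_
    )

    collection <- list(); chambers <- list(); truth_rows <- list()
    ledger_rows <- list()

    for (a in seq_len(n_animal)) {
      # per-animal physiological draws
      base_intake <- sample_intake(avg_bw[a], temps[a], p$intake_coeffs,
                                   p$intake_noise_sd)
      de_ge <- rnorm_clamped(1, p$de_ge_mean, p$de_ge_sd, 0.5, 0.99)
      urine_frac <- rnorm_clamped(1, p$urine_e_frac_mean, p$urine_e_frac_sd, 0, 0.1)
      ch4_frac <- rnorm_clamped(1, p$ch4_e_frac_mean, p$ch4_e_frac_sd, 0, 0.05)
      fecal_n_frac <- rnorm_clamped(1, p$fecal_n_frac_mean, p$fecal_n_frac_sd, 0, 0.5)
      urine_n_frac <- rnorm_clamped(1, p$urine_n_frac_mean, p$urine_n_frac_sd, 0, 0.5)
      rq_fed <- rnorm_clamped(1, p$rq_fed_mean, p$rq_fed_sd, 0.7, 1.3)
      rq_fast <- rnorm_clamped(1, p$rq_fast_mean, p$rq_fast_sd, 0.7, 1.3)
      fhp_mbw <- rnorm_clamped(1, p$fhp_mean, p$fhp_sd, 100)
      thp_dev <- stats::rnorm(1, 0, p$thp_sd)

      day_noise <- if (p$intake_day_sd > 0)
        exp(stats::rnorm(n_days, -p$intake_day_sd^2 / 2, p$intake_day_sd)) else
          rep(1, n_days)
      feed <- base_intake * day_noise

      ge <- feed * ge_kJ_per_kg
      fecal_e <- (1 - de_ge) * ge
      de <- ge - fecal_e
      urine_e <- urine_frac * de
      ch4_e <- ch4_frac * de
      ch4_L <- ch4_e / k$methane_energy_kJ_per_L
      me <- de - urine_e - ch4_e

      n_intake <- feed * n_per_kg_feed
      fecal_n <- fecal_n_frac * n_intake
      urine_n <- urine_n_frac * n_intake

      # fed THP rises with ME intake on the metabolic-bodyweight basis
      thp_mbw <- pmax(p$thp_intercept + p$thp_slope * me / mbw[a] + thp_dev, 50)
      thp <- thp_mbw * mbw[a]
      # gas volumes that close the Brouwer identity exactly at the drawn RQ
      o2 <- (thp + k$brouwer_n * urine_n + k$brouwer_ch4 * ch4_L) /
        (k$brouwer_o2 + k$brouwer_co2 * rq_fed)
      co2 <- rq_fed * o2

      # fasting day
      fhp <- fhp_mbw * mbw[a]
      fast_urine_n <- p$fast_urine_n_frac * mean(urine_n)
      o2_f <- (fhp + k$brouwer_n * fast_urine_n) /
        (k$brouwer_o2 + k$brouwer_co2 * rq_fast)
      co2_f <- rq_fast * o2_f

      animals$fast_urine_n_g[a] <- fast_urine_n

      daily <- data.frame(
        day = seq_len(fast_day),
        o2_L = c(o2, o2_f), co2_L = c(co2, co2_f), ch4_L = c(ch4_L, 0)
      )
      chambers[[ids[a]]] <- gas_log_from_truth(
        daily, design$airflow_L_per_min, design$sampling_interval_min,
        fast_days = fast_day, noise_pp = p$analyzer_noise_pp,
        window_factor = p$window_factor
      )

      collection[[a]] <- data.frame(
        animal = ids[a], day = seq_len(n_days),
        feed_kg = feed, feces_kg = 0.5 * feed,
        urine_L = 1.5 + 0.02 * avg_bw[a],
        fecal_ge_kJ = fecal_e, urine_ge_kJ = urine_e,
        fecal_n_g = fecal_n, urine_n_g = urine_n
      )

      truth_rows[[a]] <- data.frame(
        animal = ids[a], day = seq_len(fast_day),
        state = c(rep("fed", n_days), "fast"),
        intake_kg = c(feed, 0),
        o2_L = daily$o2_L, co2_L = daily$co2_L, ch4_L = daily$ch4_L,
        urine_n_g = c(urine_n, fast_urine_n),
        fecal_e_kJ = c(fecal_e, 0), urine_e_kJ = c(urine_e, 0),
        thp_kJ = c(thp, fhp),
        rq = c(rep(rq_fed, n_days), rq_fast)
      )

      me_mbw <- mean(me) / mbw[a]
      thp_mean_mbw <- mean(thp) / mbw[a]
      n_ret <- mean(n_intake) - mean(fecal_n) - mean(urine_n)
      re <- me_mbw - thp_mean_mbw
      re_p <- n_ret * k$n_to_protein * k$protein_energy_kJ_per_g / mbw[a]
      ledger_rows[[a]] <- data.frame(
        animal = ids[a], temp_C = temps[a], avg_bw_kg = avg_bw[a],
        mbw = mbw[a], vfi_kg_d = mean(feed),
        ge = mean(ge) / mbw[a], de = mean(de) / mbw[a], me_i = me_mbw,
        thp = thp_mean_mbw, fhp = fhp_mbw,
        re = re, re_p = re_p, re_l = re - re_p, ne = re + fhp_mbw,
        rq_fed = rq_fed, rq_fast = rq_fast,
        n_intake_g_d = mean(n_intake), n_fecal_g_d = mean(fecal_n),
        n_urine_g_d = mean(urine_n), n_retention_g_d = n_ret
      )
    }

    structure(list(
      design = design, truth_params = p,
      animals = animals,
      collection = do.call(rbind, collection),
      chambers = chambers,
      truth = list(
        animal_day = do.call(rbind, truth_rows),
        ledger = do.call(rbind, ledger_rows),
        coefficients = p$intake_coeffs
      )
    ), class = "calorimetry_trial")
  })
}

#' @export
print.calorimetry_trial <- function(x, ...) {
  d <- x$design
  cat("Synthetic respiration-chamber trial (stage ", d$stage_label, ")\n",
      sep = "")
  cat("  temperatures: ", paste(d$temperatures_C, collapse = ", "),
      " degC x ", d$replicates_per_temperature, " replicates = ",
      nrow(x$animals), " animals\n", sep = "")
  cat("  ", d$n_balance_days, " fed balance days + 1 fasting day, gas every ",
      d$sampling_interval_min, " min\n", sep = "")
  invisible(x)
}

#' Simulate a plasma metabolite feature table
#'
#' Log-normal feature intensities for three temperature groups (`low`,
#' `neutral`, `high`), with a chosen subset of features planted with true
#' group fold changes (relative to the neutral group) and all remaining
#' features sharing one group mean. Intensities are strictly positive.
#'
#' @param n_samples_per_group samples per group.
#' @param n_features number of features.
#' @param planted data.frame with columns `feature` (index), `fc_high`,
#'   `fc_low` (true fold changes vs the neutral group, > 0); NULL for none.
#' @param base_log_mean,base_log_sd log-scale distribution of feature
#'   baseline intensities.
#' @param noise_log_sd log-scale within-group noise SD (0.08 gives a
#'   within-group CV of about 8%).
#' @param seed integer seed.
#' @return list of class `feature_table`: `x` (samples x features intensity
#'   matrix), `group` (factor low/neutral/high), `planted`.
#' @examples
#' ft <- simulate_feature_table(6, 50,
#'         planted = data.frame(feature = 1:3, fc_high = 4, fc_low = 1),
#'         seed = 7)
#' dim(ft$x)
#' @export
simulate_feature_table <- function(n_samples_per_group = 6, n_features = 200,
                                   planted = NULL, base_log_mean = log(1e4),
                                   base_log_sd = 0.5, noise_log_sd = 0.08,
                                   seed = 1) {
  if (!is.null(planted)) {
    stopifnot(all(c("feature", "fc_high", "fc_low") %in% names(planted)))
    if (any(planted$fc_high <= 0) || any(planted$fc_low <= 0))
      stop("parameter error: planted fold changes must be positive")
    if (any(planted$feature < 1) || any(planted$feature > n_features))
      stop("parameter error: planted feature index outside the table")
  }
  with_seed(seed, {
    groups <- factor(rep(c("low", "neutral", "high"), each = n_samples_per_group),
                     levels = c("low", "neutral", "high"))
    n <- length(groups)
    base <- exp(stats::rnorm(n_features, base_log_mean, base_log_sd))
    mult <- matrix(1, n, n_features)
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        j <- planted$feature[i]
        mult[groups == "high", j] <- planted$fc_high[i]
        mult[groups == "low", j] <- planted$fc_low[i]
      }
    }
    noise <- matrix(exp(stats::rnorm(n * n_features, 0, noise_log_sd)),
                    n, n_features)
    x <- sweep(mult * noise, 2, base, `*`)
    dimnames(x) <- list(sprintf("s%02d", seq_len(n)),
                        sprintf("feat_%03d", seq_len(n_features)))
    structure(list(x = x, group = groups, planted = planted),
              class = "feature_table")
  })
}
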