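#' Per-animal nitrogen and energy ledger
#'
#' Runs the full indirect-calorimetry bookkeeping for every animal of a
#' trial bundle: daily gas volumes from the chamber log (collection windows
#' excluded and rescaled to 24 h), fed-state means over the balance days,
#' heat production by the Brouwer equation, fasting heat production from the
#' 22:00-06:00 fasting night extrapolated to 24 h, the GE/DE/ME/NE cascade,
#' retained energy and its protein/lipid partition, respiratory quotients,
#' utilization ratios, and heat production adjusted to the reference ME
#' intake (within-trial regression; `NA` when the cohort is too small or its
#' ME spread degenerate). All rates are reported per kg metabolic bodyweight
#' (BW^0.6) per day; bodyweight is the mean of chamber entry and exit
#' weights.
#'
#' @param trial a `calorimetry_trial` bundle from [simulate_trial()] or
#'   [read_trial()].
#' @param constants a [calorimetry_constants()] bundle.
#' @param windows collection exclusion windows, as [exclusion_windows()].
#' @return data.frame, one row per animal: identifiers, bodyweights,
#'   `vfi_kg_d`, energy intakes `ge`, `de`, `me_i`, `ne` and heat terms
#'   `thp`, `thp_adjusted`, `fhp`, retention `re`, `re_p`, `re_l`
#'   (kJ/kg BW^0.6/d), `rq_fed`, `rq_fast`, nitrogen balance (g/d),
#'   utilization percentages and the animal's lower critical temperature.
#' @examples
#' tr <- simulate_trial(trial_design("toy", c(18, 32), 2, 30, 1,
#'                                   n_balance_days = 2), seed = 1)
#' energy_ledger(tr)[, c("animal", "me_i", "thp", "re")]
#' @export
energy_ledger <- function(trial, constants = calorimetry_constants(),
                          windows = exclusion_windows()) {
  stopifnot(inherits(trial, "calorimetry_trial"))
  k <- constants
  n_fed <- trial$design$n_balance_days
  diet <- trial$design$diet
  rows <- lapply(seq_len(nrow(trial$animals)), function(i) {
    an <- trial$animals[i, ]
    log <- trial$chambers[[an$animal]]
    gas <- compute_gas_volumes(log, windows)
    gas <- gas[order(gas$day), ]
    if (nrow(gas) < n_fed + 1)
      stop("chamber log for ", an$animal, " does not cover the balance period")
    fed <- gas[seq_len(n_fed), ]
    fw <- fasting_window_volumes(log)

    coll <- trial$collection[trial$collection$animal == an$animal, ]
    if (nrow(coll) != n_fed)
      stop("collection table for ", an$animal, " has ", nrow(coll),
           " rows, expected ", n_fed)

    mbw <- metabolic_bw(an$avg_bw_kg, k$metabolic_exponent)
    feed <- mean(coll$feed_kg)
    ge <- feed * diet$ge_MJ_per_kg * 1000
    ei <- energy_intakes(ge, mean(coll$fecal_ge_kJ), mean(coll$urine_ge_kJ),
                         mean(fed$ch4_L), constants = k)

    urine_n <- mean(coll$urine_n_g)
    thp <- heat_production(mean(fed$o2_L), mean(fed$co2_L), mean(fed$ch4_L),
                           urine_n, constants = k)
    fhp <- heat_production(fw$o2_24h, fw$co2_24h, fw$ch4_24h,
                           an$fast_urine_n_g, constants = k)

    nb <- nitrogen_balance(feed * diet$cp_fraction / k$n_to_protein * 1000,
                           mean(coll$fecal_n_g), urine_n)
    rp <- retention_partition(ei$me_kJ / mbw, thp / mbw, nb$retention_g_d,
                              an$avg_bw_kg, constants = k)
    ne <- net_energy(rp$re, fhp / mbw)
    ur <- utilization_ratios(ge, ei$de_kJ, ei$me_kJ, ne * mbw,
                             mean(coll$urine_ge_kJ), ei$ch4_e_kJ)

    cbind(
      data.frame(animal = an$animal, stage = an$stage, temp_C = an$temp_C,
                 avg_bw_kg = an$avg_bw_kg, mbw = mbw, vfi_kg_d = feed,
                 ge = ge / mbw, de = ei$de_kJ / mbw, me_i = ei$me_kJ / mbw,
                 ne = ne, thp = thp / mbw, thp_adjusted = NA_real_,
                 fhp = fhp / mbw),
      rp,
      data.frame(rq_fed = mean(fed$co2_L) / mean(fed$o2_L), rq_fast = fw$rq,
                 n_intake_g_d = nb$intake_g_d, n_fecal_g_d = nb$fecal_g_d,
                 n_urine_g_d = nb$urine_g_d, n_retention_g_d = nb$retention_g_d),
      ur,
      data.frame(lct_C = lct(an$avg_bw_kg, k))
    )
  })
  ledger <- do.call(rbind, rows)
  ledger$thp_adjusted <- tryCatch(
    adjusted_thp(ledger$thp, ledger$me_i, k$reference_mei_kJ_per_kgMBW)$adjusted,
    error = function(e) rep(NA_real_, nrow(ledger))
  )
  rownames(ledger) <- NULL
  ledger
}

#' Write and read a trial bundle as plain-text files
#'
#' `write_trial()` emits the standard file set of a chamber trial into a
#' directory: `chamber_<animal>.csv` (timestamped concentration/flow log),
#' `collection.csv`, `animals.csv` and, when ground truth is present,
#' `truth.json`. `read_trial()` reconstructs the bundle; a diet/design
#' description is carried in `design.json`.
#'
#' @param trial a `calorimetry_trial`.
#' @param dir target directory (created if absent).
#' @return `write_trial()`: the directory, invisibly. `read_trial()`: a
#'   `calorimetry_trial`.
#' @examples
#' tr <- simulate_trial(trial_design("toy", c(18, 32), 1, 30, 0,
#'                                   n_balance_days = 2), seed = 1)
#' d <- file.path(tempdir(), "toytrial")
#' write_trial(tr, d)
#' tr2 <- read_trial(d)
#' identical(tr$animals$animal, tr2$animals$animal)
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "calorimetry_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(trial$chambers)) {
    log <- trial$chambers[[id]]
    log$timestamp <- format(log$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    utils::write.csv(log, file.path(dir, paste0("chamber_", id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(trial$collection, file.path(dir, "collection.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$animals, file.path(dir, "animals.csv"),
                   row.names = FALSE)
  design <- trial$design
  design$diet <- unclass(design$diet)
  jsonlite::write_json(unclass(design), file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(trial$truth)) {
    truth <- trial$truth
    truth$coefficients <- as.list(truth$coefficients)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  dj <- jsonlite::read_json(file.path(dir, "design.json"), simplifyVector = TRUE)
  design <- trial_design(dj$stage_label, dj$temperatures_C,
                         dj$replicates_per_temperature, dj$initial_bw_mean_kg,
                         dj$initial_bw_sd_kg,
                         diet_spec(dj$diet$dm_fraction, dj$diet$ge_MJ_per_kg,
                                   dj$diet$cp_fraction),
                         dj$n_balance_days, dj$sampling_interval_min,
                         dj$airflow_L_per_min)
  animals <- utils::read.csv(file.path(dir, "animals.csv"))
  collection <- utils::read.csv(file.path(dir, "collection.csv"))
  chambers <- lapply(animals$animal, function(id) {
    log <- utils::read.csv(file.path(dir, paste0("chamber_", id, ".csv")))
    log$timestamp <- as.POSIXct(log$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC")
    log
  })
  names(chambers) <- animals$animal
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth$coefficients <- unlist(truth$coefficients)
  }
  structure(list(design = design, truth_params = NULL, animals = animals,
                 collection = collection, chambers = chambers, truth = truth),
            class = "calorimetry_trial")
}
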