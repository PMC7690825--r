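#' Heat production by the Brouwer equation
#'
#' `HP (kJ) = 16.18 O2 (L) + 5.02 CO2 (L) - 2.17 CH4 (L) - 5.99 urinary N (g)`,
#' the standard linear combination converting respiratory gas exchange and
#' urinary nitrogen into heat production. Exact, unrounded; vectorised.
#'
#' @param o2_L oxygen consumed (L, STPD).
#' @param co2_L carbon dioxide produced (L).
#' @param ch4_L methane produced (L).
#' @param urinary_n_g urinary nitrogen excreted (g).
#' @param constants a [calorimetry_constants()] bundle.
#' @return heat production in kJ.
#' @examples
#' heat_production(100, 80, 0, 10)   # 1959.7 kJ
#' @export
heat_production <- function(o2_L, co2_L, ch4_L = 0, urinary_n_g = 0,
                            constants = calorimetry_constants()) {
  inputs <- cbind(o2_L, co2_L, ch4_L, urinary_n_g)
  if (any(!is.finite(inputs)) || any(inputs < 0))
    stop("gas volumes and urinary N must be nonnegative and finite")
  constants$brouwer_o2 * o2_L + constants$brouwer_co2 * co2_L -
    constants$brouwer_ch4 * ch4_L - constants$brouwer_n * urinary_n_g
}

#' Daily nitrogen balance
#'
#' Retention is intake minus fecal and urinary output, all in g N/day.
#'
#' @param intake_g_d,fecal_g_d,urine_g_d nitrogen flows, g/d (vectorised,
#'   nonnegative).
#' @return data.frame with columns `intake_g_d`, `fecal_g_d`, `urine_g_d`,
#'   `retention_g_d`.
#' @examples
#' nitrogen_balance(41.9, 6.7, 5.4)$retention_g_d  # 29.8
#' @export
nitrogen_balance <- function(intake_g_d, fecal_g_d, urine_g_d) {
  inputs <- cbind(intake_g_d, fecal_g_d, urine_g_d)
  if (any(!is.finite(inputs)) || any(inputs < 0))
    stop("nitrogen flows must be nonnegative and finite")
  data.frame(
    intake_g_d = intake_g_d, fecal_g_d = fecal_g_d, urine_g_d = urine_g_d,
    retention_g_d = intake_g_d - fecal_g_d - urine_g_d
  )
}

#' Digestible and metabolizable energy intake
#'
#' DE is gross energy intake minus fecal energy; ME is DE minus urinary
#' energy and methane energy (methane volume times 39.4 kJ/L). All in kJ/d.
#'
#' @param ge_intake_kJ gross energy intake.
#' @param fecal_e_kJ fecal energy loss.
#' @param urine_e_kJ urinary energy loss.
#' @param ch4_L methane produced (L/d).
#' @param constants a [calorimetry_constants()] bundle.
#' @return data.frame with `de_kJ`, `me_kJ`, `ch4_e_kJ`.
#' @examples
#' energy_intakes(1000, 150, 10, 0)  # DE 850, ME 840
#' @export
energy_intakes <- function(ge_intake_kJ, fecal_e_kJ, urine_e_kJ, ch4_L,
                           constants = calorimetry_constants()) {
  inputs <- cbind(ge_intake_kJ, fecal_e_kJ, urine_e_kJ, ch4_L)
  if (any(!is.finite(inputs)) || any(inputs < 0))
    stop("energy flows and methane volume must be nonnegative and finite")
  de <- ge_intake_kJ - fecal_e_kJ
  ch4_e <- constants$methane_energy_kJ_per_L * ch4_L
  me <- de - urine_e_kJ - ch4_e
  if (any(de < 0) || any(me < 0))
    stop("computed DE or ME is negative: inconsistent energy inputs")
  data.frame(de_kJ = de, me_kJ = me, ch4_e_kJ = ch4_e)
}

#' Retained energy and its protein/lipid partition
#'
#' On the per-kg-metabolic-bodyweight basis: retained energy is ME intake
#' minus total heat production; the protein fraction is nitrogen retention
#' times 6.25 (protein per g N) times 23.86 kJ/g body protein, divided by
#' BW^0.6; lipid retention is the remainder. Lipid retention may legitimately
#' be negative (mobilisation) and is reported as computed.
#'
#' @param me_i metabolizable energy intake, kJ/kg BW^0.6/d.
#' @param thp total heat production, kJ/kg BW^0.6/d.
#' @param n_retention_g_d nitrogen retention, g/d (whole animal).
#' @param avg_bw_kg average bodyweight of the period, kg.
#' @param constants a [calorimetry_constants()] bundle.
#' @return data.frame with `re`, `re_p`, `re_l` in kJ/kg BW^0.6/d.
#' @examples
#' retention_partition(2555, 1075, 29.2, 27.0)
#' @export
retention_partition <- function(me_i, thp, n_retention_g_d, avg_bw_kg,
                                constants = calorimetry_constants()) {
  mbw <- metabolic_bw(avg_bw_kg, constants$metabolic_exponent)
  re <- me_i - thp
  re_p <- n_retention_g_d * constants$n_to_protein *
    constants$protein_energy_kJ_per_g / mbw
  data.frame(re = re, re_p = re_p, re_l = re - re_p)
}

#' Net energy intake
#'
#' Net energy is retained energy plus maintenance energy, the latter
#' estimated by fasting heat production. Both inputs must be on the same
#' basis (kJ/kg BW^0.6/d here).
#'
#' @param re retained energy.
#' @param fhp fasting heat production.
#' @return `re + fhp`.
#' @examples
#' net_energy(1565, 716)  # 2281
#' @export
net_energy <- function(re, fhp) re + fhp

#' Respiratory quotient
#'
#' Ratio of CO2 produced to O2 consumed, unrounded.
#'
#' @param co2_L,o2_L daily gas volumes (L); `o2_L` must be positive.
#' @return dimensionless RQ.
#' @examples
#' respiratory_quotient(1440, 1800)  # 0.8
#' @export
respiratory_quotient <- function(co2_L, o2_L) {
  if (any(!is.finite(o2_L)) || any(o2_L <= 0))
    stop("RQ undefined: O2 consumption must be positive")
  co2_L / o2_L
}

#' Adjust heat production to a common ME intake
#'
#' To remove the feeding-level effect, total heat production is adjusted to a
#' reference ME intake (2.4 MJ/kg BW^0.6/d by default) using the within-cohort
#' least-squares slope of THP on ME intake, both per kg BW^0.6:
#' `adjusted = thp + beta * (reference - me_i)`.
#'
#' @param thp total heat production, kJ/kg BW^0.6/d (one value per animal).
#' @param me_i metabolizable energy intake, kJ/kg BW^0.6/d.
#' @param reference_mei reference intake level, kJ/kg BW^0.6/d.
#' @return list with `adjusted` (per animal), `beta` (kJ heat per kJ ME).
#' @examples
#' adjusted_thp(c(900, 1100, 1000), c(2000, 2800, 2400))
#' @export
adjusted_thp <- function(thp, me_i,
                         reference_mei = calorimetry_constants()$reference_mei_kJ_per_kgMBW) {
  if (length(thp) != length(me_i)) stop("thp and me_i lengths differ")
  if (length(thp) < 2 || stats::sd(me_i) < sqrt(.Machine$double.eps) * max(1, mean(abs(me_i))))
    stop("cannot adjust THP: ME intake spread is degenerate")
  beta <- unname(stats::coef(stats::lm(thp ~ me_i))[2])
  list(adjusted = thp + beta * (reference_mei - me_i), beta = beta)
}

#' Energy utilization ratios
#'
#' The percentage efficiencies of the energy ledger: DE/GE, ME/DE, NE/ME, and
#' the urinary-energy and methane-energy losses as a percentage of DE.
#' Unrounded; any required denominator must be positive.
#'
#' @param ge,de,me,ne energy intakes on a common basis.
#' @param urine_e,ch4_e urinary and methane energy losses, same basis.
#' @return data.frame with `de_ge`, `me_de`, `ne_me`, `urine_e_de`,
#'   `ch4_e_de`, in percent.
#' @examples
#' utilization_ratios(3000, 2550, 2500, 2100, 30, 12.75)
#' @export
utilization_ratios <- function(ge, de, me, ne, urine_e = NA_real_, ch4_e = NA_real_) {
  if (any(ge <= 0) || any(de <= 0) || any(me <= 0))
    stop("ratio undefined: zero or negative denominator")
  data.frame(
    de_ge = 100 * de / ge,
    me_de = 100 * me / de,
    ne_me = 100 * ne / me,
    urine_e_de = 100 * urine_e / de,
    ch4_e_de = 100 * ch4_e / de
  )
}
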