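test_that("Brouwer heat production matches hand arithmetic and is linear", {
  expect_equal(heat_production(0, 0, 0, 0), 0)
  # 16.18*100 + 5.02*80 - 5.99*10 = 1618 + 401.6 - 59.9
  expect_equal(heat_production(100, 80, 0, 10), 1959.7)
  # 16.18*500 + 5.02*500 - 2.17*5 - 5.99*20
  expect_equal(heat_production(500, 500, 5, 20), 10469.35)

  # additivity and homogeneity in all four inputs
  set.seed(11)
  for (i in 1:20) {
    x <- runif(4, 0, 500); y <- runif(4, 0, 500); k <- runif(1, 0, 3)
    hp <- function(v) heat_production(v[1], v[2], v[3], v[4])
    expect_equal(hp(x + y), hp(x) + hp(y), tolerance = 1e-12)
    expect_equal(hp(k * x), k * hp(x), tolerance = 1e-12)
  }
  expect_error(heat_production(-1, 0, 0, 0), "nonnegative")
})

test_that("nitrogen balance is intake minus fecal and urinary output", {
  expect_equal(nitrogen_balance(41.9, 6.7, 5.4)$retention_g_d, 29.8)
  expect_equal(nitrogen_balance(36.8, 4.6, 6.0)$retention_g_d, 26.2)
  expect_equal(nitrogen_balance(0, 0, 0)$retention_g_d, 0)
  expect_error(nitrogen_balance(-1, 0, 0), "nonnegative")
})

test_that("DE/ME cascade and methane energy follow their definitions", {
  ei <- energy_intakes(1000, 150, 10, 0)
  expect_equal(ei$de_kJ, 850)
  expect_equal(ei$me_kJ, 840)
  expect_equal(energy_intakes(100, 0, 0, 1)$ch4_e_kJ, 39.4)
  x <- 1234.5
  ei0 <- energy_intakes(x, 0, 0, 0)
  expect_equal(ei0$de_kJ, x)
  expect_equal(ei0$me_kJ, x)
  expect_error(energy_intakes(100, 150, 0, 0), "negative")
})

test_that("retention partition and net energy reproduce the ledger identities", {
  expect_equal(retention_partition(2555, 1075, 29.2, 27.0)$re, 1480)
  # RE_P = 29.2 * 6.25 * 23.86 / 27^0.6, within 0.5% of the printed 602
  rp <- retention_partition(2555, 1075, 29.2, 27.0)
  expect_equal(rp$re_p, 602, tolerance = 0.005)
  expect_equal(rp$re_l, rp$re - rp$re_p)
  # lipid retention may be negative and is not clamped
  expect_lt(retention_partition(1000, 900, 20, 30)$re_l, 0)
  expect_equal(net_energy(0, 0), 0)
  expect_equal(net_energy(1565, 716), 2281)
  expect_equal(net_energy(2128, 731), 2859)
})

test_that("metabolic bodyweight and LCT formulas evaluate exactly", {
  expect_equal(metabolic_bw(1), 1)
  expect_equal(metabolic_bw(28.7), exp(0.6 * log(28.7)))
  expect_equal(metabolic_bw(64), exp(0.6 * log(64)))
  expect_error(metabolic_bw(0), "positive")
  expect_equal(lct(0), 17.9)
  expect_equal(lct(26.4), 17.9 - 0.0375 * 26.4)
  expect_equal(lct(64.2), 15.4925)
})

test_that("THP adjustment to the reference ME intake uses the cohort slope", {
  # two-point regression oracle: slope 200/800 = 0.25, both adjust to 1000
  adj <- adjusted_thp(c(900, 1100), c(2000, 2800))
  expect_equal(adj$beta, 0.25)
  expect_equal(adj$adjusted, c(1000, 1000))
  # an animal already at the reference level is unchanged for any slope
  adj2 <- adjusted_thp(c(950, 1000, 1100), c(2100, 2400, 2900))
  expect_equal(adj2$adjusted[2], 1000)
  # flat cohort: beta = 0, adjusted = thp
  adj3 <- adjusted_thp(c(1000, 1000, 1000), c(2000, 2400, 2800))
  expect_equal(adj3$adjusted, c(1000, 1000, 1000))
  expect_error(adjusted_thp(c(1, 2), c(5, 5)), "degenerate")
})

test_that("utilization ratios are exact percentages", {
  expect_equal(utilization_ratios(100, 100, 90, 80)$de_ge, 100)
  expect_equal(utilization_ratios(3000, 2550, 2500, 2100, 30, 12.75)$de_ge, 85)
  expect_equal(utilization_ratios(3000, 2550, 2500, 2100, 30, 12.75)$ch4_e_de, 0.5)
  expect_error(utilization_ratios(0, 1, 1, 1), "denominator")
})

test_that("ledger closure holds on a noisy synthetic trial", {
  tr <- simulate_trial(trial_design("toy", c(18, 25, 32), 3, 30, 1.5,
                                    n_balance_days = 3), seed = 42)
  led <- energy_ledger(tr)
  expect_equal(led$re, led$me_i - led$thp, tolerance = 1e-9)
  expect_equal(led$re, led$re_p + led$re_l, tolerance = 1e-9)
  expect_equal(led$ne, led$re + led$fhp, tolerance = 1e-9)
  expect_true(all(led$de <= led$ge))
  expect_true(all(led$me_i <= led$de))
})

test_that("per-MBW quantities scale as BW^-0.6 when bodyweight is perturbed", {
  k <- 1.7
  rp1 <- retention_partition(2500, 1000, 30, 40)
  rp2 <- retention_partition(2500, 1000, 30, 40 * k)
  expect_equal(rp2$re_p, rp1$re_p / k^0.6, tolerance = 1e-12)
})
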