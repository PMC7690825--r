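test_that("trial design invariants are enforced", {
  expect_error(trial_design("x", numeric(0), 6, 25, 1), "empty temperature")
  expect_error(trial_design("x", c(20, 18), 6, 25, 1), "strictly increasing")
  expect_error(trial_design("x", c(18, 32), 0, 25, 1), "replicates")
  expect_error(trial_design("x", c(18, 32), 6, 25, 1,
                            sampling_interval_min = 7), "divide 1440")
  d <- trial_design_25kg()
  expect_equal(d$temperatures_C, c(18, 21, 23, 27, 29, 32))
  expect_equal(trial_design_65kg()$temperatures_C, c(18, 23, 27, 32))
})

test_that("simulation is deterministic under a fixed seed", {
  d <- trial_design("toy", c(18, 32), 2, 30, 1, n_balance_days = 2)
  t1 <- simulate_trial(d, seed = 42)
  t2 <- simulate_trial(d, seed = 42)
  expect_identical(t1, t2)
  t3 <- simulate_trial(d, seed = 43)
  expect_false(identical(t1$collection, t3$collection))
})

test_that("a six-by-six design yields 36 animals with full chamber logs", {
  tr <- simulate_trial(trial_design_25kg(), seed = 42)
  expect_equal(nrow(tr$animals), 36)
  expect_length(tr$chambers, 36)
  # 5 fed days + 1 fast day + 6 h spillover, at 288 samples/day
  rows_expected <- (5 + 1) * 288 + 72
  expect_true(all(vapply(tr$chambers, nrow, integer(1)) == rows_expected))
  # collection windows are marked on fed days only
  log <- tr$chambers[[1]]
  expect_equal(sum(log$collection_window), 5 * 12)
  expect_equal(nrow(tr$collection), 36 * 5)
})

test_that("sampled intake follows the quadratic surface", {
  cf <- pig_surface_coefficients()$vfi
  # independent hand evaluation of the polynomial at BW 28.7, T 18
  m <- 28.7^0.6
  by_hand <- -7.72 + 1.54 * m - 0.059 * m^2 + 0.15 * 18 -
    0.0022 * 18^2 - 0.0088 * m * 18
  expect_equal(sample_intake(28.7, 18, cf, noise_sd = 0), by_hand)
  expect_equal(by_hand, 1.3, tolerance = 0.01)
  # all-zero coefficients give zero intake
  zero <- setNames(rep(0, 6), letters[1:6])
  expect_equal(sample_intake(30, 25, zero, noise_sd = 0), 0)
  # repeated noiseless calls are identical
  expect_equal(sample_intake(40, 20, cf, 0), sample_intake(40, 20, cf, 0))
  # surface is truncated at zero from below
  neg <- setNames(c(-5, 0, 0, 0, 0, 0), letters[1:6])
  expect_equal(sample_intake(30, 25, neg, noise_sd = 0), 0)
})

test_that("mean simulated intake declines from 18 to 32 degC at the heavy stage", {
  cf <- pig_surface_coefficients()$vfi
  expect_lt(sample_intake(69, 32, cf, 0), sample_intake(69, 18, cf, 0))
  set.seed(8)
  m18 <- mean(sample_intake(rep(69, 500), 18, cf, 0.12))
  m32 <- mean(sample_intake(rep(69, 500), 32, cf, 0.12))
  expect_lt(m32, m18)
})

test_that("true THP closes the Brouwer identity exactly for every animal-day", {
  tr <- simulate_trial(trial_design("toy", c(18, 25, 32), 2, 28, 2,
                                    n_balance_days = 3), seed = 7)
  ad <- tr$truth$animal_day
  hp <- heat_production(ad$o2_L, ad$co2_L, ad$ch4_L, ad$urine_n_g)
  expect_equal(hp, ad$thp_kJ, tolerance = 1e-12)
  expect_true(all(ad$rq >= 0.7 & ad$rq <= 1.3))
})

test_that("zero-noise pipeline reproduces the simulator ground truth", {
  tr <- simulate_trial(trial_design("toy", c(18, 24, 32), 2, 30, 0),
                       trial_truth_params(noise_scale = 0), seed = 1)
  led <- energy_ledger(tr)
  truth <- tr$truth$ledger
  for (col in c("vfi_kg_d", "ge", "de", "me_i", "thp", "fhp", "re", "re_p",
                "re_l", "ne", "rq_fed", "rq_fast", "n_retention_g_d")) {
    expect_equal(led[[col]], truth[[col]], tolerance = 1e-9,
                 info = col)
  }
})

test_that("noisy pipeline recovers ledger truth within 1%", {
  tr <- simulate_trial(trial_design("toy", c(18, 32), 2, 30, 1,
                                    n_balance_days = 3), seed = 5)
  led <- energy_ledger(tr)
  truth <- tr$truth$ledger
  # only analyzer noise separates analysis from truth (collection is
  # shared); the fasting window, being 8 h extrapolated by 3, carries the
  # largest relative noise share
  for (col in c("me_i", "thp", "fhp", "re", "rq_fed", "rq_fast")) {
    rel <- abs(led[[col]] - truth[[col]]) / pmax(abs(truth[[col]]), 1)
    expect_lt(max(rel), 0.01)
  }
})

test_that("feature-table simulation is deterministic and validates planting", {
  f1 <- simulate_feature_table(4, 30, seed = 9)
  f2 <- simulate_feature_table(4, 30, seed = 9)
  expect_identical(f1, f2)
  expect_error(simulate_feature_table(
    4, 30, planted = data.frame(feature = 1, fc_high = -2, fc_low = 1)),
    "positive")
  expect_error(simulate_feature_table(
    4, 30, planted = data.frame(feature = 99, fc_high = 2, fc_low = 1)),
    "outside")
  # non-planted features share one group mean: intensities positive
  expect_true(all(f1$x > 0))
})

test_that("trial files round-trip through the plain-text writers", {
  tr <- simulate_trial(trial_design("toy", c(18, 32), 1, 30, 0,
                                    n_balance_days = 2), seed = 3)
  d <- file.path(tempdir(), "trial_io_test")
  write_trial(tr, d)
  expect_true(file.exists(file.path(d, "collection.csv")))
  expect_true(file.exists(file.path(d, "truth.json")))
  tr2 <- read_trial(d)
  led1 <- energy_ledger(tr)
  led2 <- energy_ledger(tr2)
  expect_equal(led2$me_i, led1$me_i, tolerance = 1e-9)
  expect_equal(led2$thp, led1$thp, tolerance = 1e-9)
  unlink(d, recursive = TRUE)
})
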