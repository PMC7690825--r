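# fabricate a constant-differential chamber log directly (independent of the
# package's generator)
make_constant_log <- function(days = 1, o2_def_pp = 0.5, co2_exc_pp = 0.5,
                              ch4_exc_pp = 0, flow = 250, interval = 5) {
  n_per_day <- 1440 / interval
  ts <- as.POSIXct("2020-01-01", tz = "UTC") +
    seq(0, days * 86400 - interval * 60, by = interval * 60)
  data.frame(
    timestamp = ts,
    o2_in_pct = 20.95, o2_out_pct = 20.95 - o2_def_pp,
    co2_in_pct = 0.04, co2_out_pct = 0.04 + co2_exc_pp,
    ch4_in_pct = 0, ch4_out_pct = ch4_exc_pp,
    flow_L_min = flow
  )
}

test_that("a constant 0.5-pp O2 deficit at 250 L/min integrates to 1800 L/d", {
  log <- make_constant_log()
  v <- compute_gas_volumes(log, exclusion_windows(character(0)))
  expect_equal(v$o2_L, 250 * 0.005 * 1440)   # 1800
  expect_equal(v$minutes_excluded, 0)
})

test_that("identical inlet and outlet concentrations give zero volumes", {
  log <- make_constant_log(o2_def_pp = 0, co2_exc_pp = 0)
  v <- compute_gas_volumes(log)
  expect_equal(v$o2_L, 0)
  expect_equal(v$co2_L, 0)
  expect_equal(v$ch4_L, 0)
})

test_that("excluding collection windows and rescaling leaves a constant signal unchanged", {
  log <- make_constant_log(days = 2)
  v_no <- compute_gas_volumes(log, exclusion_windows(character(0)))
  v_ex <- compute_gas_volumes(log)
  expect_equal(v_ex$o2_L, v_no$o2_L, tolerance = 1e-12)
  expect_equal(v_ex$co2_L, v_no$co2_L, tolerance = 1e-12)
  expect_equal(v_ex$minutes_excluded, c(60, 60))
})

test_that("volumes are linear in the concentration differential", {
  for (k in c(0.3, 1, 1.8)) {
    v <- compute_gas_volumes(make_constant_log(o2_def_pp = 0.5 * k,
                                               co2_exc_pp = 0.4 * k))
    expect_equal(v$o2_L, k * 1800, tolerance = 1e-9)
    expect_equal(v$co2_L, k * 1440, tolerance = 1e-9)
  }
})

test_that("volumes are recovered after sorting a shuffled log", {
  log <- make_constant_log()
  set.seed(3)
  shuffled <- log[sample(nrow(log)), ]
  sorted <- shuffled[order(shuffled$timestamp), ]
  expect_equal(compute_gas_volumes(sorted), compute_gas_volumes(log))
  # unsorted input is rejected rather than silently misintegrated
  expect_error(compute_gas_volumes(shuffled), "increasing")
})

test_that("negative-volume QC distinguishes noise from bad data", {
  log <- make_constant_log()
  log$ch4_out_pct <- -1e-9 + 0 * log$ch4_out_pct   # impossible reading
  expect_error(compute_gas_volumes(log), "\\[0, 100\\]")
  # strongly negative differential on a gas -> QC error naming it
  log2 <- make_constant_log(co2_exc_pp = -0.02)
  expect_error(compute_gas_volumes(log2), "negative daily co2")
})

test_that("respiratory quotient is the plain volume ratio", {
  expect_equal(respiratory_quotient(1800, 1800), 1)
  expect_equal(respiratory_quotient(1440, 1800), 0.8)
  expect_equal(respiratory_quotient(1890, 1800), 1.05)
  expect_error(respiratory_quotient(100, 0), "positive")
})

test_that("fasting window spans midnight and extrapolates by 3", {
  # two days at constant rates; window is 22:00 day2 - 06:00 day3 spillover
  truth <- data.frame(day = 1:2, o2_L = c(1800, 900), co2_L = c(1890, 720),
                      ch4_L = c(10, 2))
  log <- gas_log_from_truth(truth, fast_days = 2)
  fw <- fasting_window_volumes(log)
  expect_equal(fw$factor, 3)
  expect_equal(fw$o2_24h, 3 * fw$o2_8h)
  # constant rate all night: extrapolated volume equals the fast day's truth
  expect_equal(fw$o2_24h, 900, tolerance = 1e-9)
  expect_equal(fw$co2_24h, 720, tolerance = 1e-9)
  expect_equal(fw$rq, 0.8, tolerance = 1e-9)
  # a log ending before 06:00 is a coverage error
  short <- log[log$timestamp < as.POSIXct("2020-01-03 04:00:00", tz = "UTC"), ]
  expect_error(fasting_window_volumes(short), "coverage")
})

test_that("generator/analyzer round trip is exact at zero noise and <0.1% with noise", {
  set.seed(99)
  for (i in 1:5) {
    truth <- data.frame(day = 1:3,
                        o2_L = runif(3, 400, 2000),
                        co2_L = runif(3, 400, 2000),
                        ch4_L = runif(3, 0, 20))
    log <- gas_log_from_truth(truth, window_factor = 0.4)
    v <- compute_gas_volumes(log)
    expect_equal(v$o2_L, truth$o2_L, tolerance = 1e-6)
    expect_equal(v$co2_L, truth$co2_L, tolerance = 1e-6)
    expect_equal(v$ch4_L, truth$ch4_L, tolerance = 1e-6)
  }
  truth <- data.frame(day = 1:3, o2_L = 1500, co2_L = 1600, ch4_L = 15)
  logn <- gas_log_from_truth(truth, noise_pp = c(o2 = 0.003, co2 = 0.002,
                                                 ch4 = 0.0002), seed = 7)
  vn <- compute_gas_volumes(logn)
  expect_lt(max(abs(vn$o2_L - truth$o2_L) / truth$o2_L), 0.001)
  expect_lt(max(abs(vn$co2_L - truth$co2_L) / truth$co2_L), 0.001)
})

test_that("out-of-range implied concentrations name the offending gas", {
  expect_error(gas_log_from_truth(data.frame(day = 1, o2_L = 6e5, co2_L = 0,
                                             ch4_L = 0)), "O2")
  expect_error(gas_log_from_truth(data.frame(day = 1, o2_L = 0, co2_L = 4e5,
                                             ch4_L = 0)), "CO2")
})
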