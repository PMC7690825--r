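test_that("one-way ANOVA matches the hand-computed decomposition", {
  # 2x3 toy: groups {1,2,3} and {5,6,7}; between SS = 24, within SS = 4,
  # F = 24 / (4/4) = 24
  v <- c(1, 2, 3, 5, 6, 7)
  g <- rep(c("a", "b"), each = 3)
  an <- anova_oneway(v, g)
  expect_equal(an$f, 24)
  expect_equal(an$mse, 1)
  expect_equal(an$means$sem, rep(sqrt(1 / 3), 2))
  # two levels: F equals the squared pooled two-sample t
  tt <- t.test(v[1:3], v[4:6], var.equal = TRUE)
  expect_equal(an$f, unname(tt$statistic)^2)
  expect_equal(an$p, tt$p.value)
})

test_that("identical values give F = 0, p = 1", {
  an <- anova_oneway(rep(5, 9), rep(1:3, each = 3))
  expect_equal(an$f, 0)
  expect_equal(an$p, 1)
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "fewer than two")
})

test_that("Tukey letters match a brute-force studentized-range oracle", {
  set.seed(14)
  for (rep_i in 1:10) {
    mus <- sample(c(0, 0, 3, 6), 3)
    v <- rnorm(12, rep(mus, each = 4), 1)
    g <- rep(c("t1", "t2", "t3"), each = 4)
    tk <- tukey_letters(v, g)
    # oracle: direct pairwise studentized-range p-values
    mse <- anova_oneway(v, g)$mse
    mns <- tapply(v, g, mean)
    for (a in names(mns)) for (b in names(mns)) {
      if (a == b) next
      q <- abs(mns[a] - mns[b]) / sqrt(mse / 4)
      p_oracle <- ptukey(q, 3, 9, lower.tail = FALSE)
      expect_equal(tk$p_matrix[a, b], unname(p_oracle), tolerance = 1e-8)
      # letters share iff p >= 0.05
      share <- any(strsplit(tk$letters[a], "")[[1]] %in%
                     strsplit(tk$letters[b], "")[[1]])
      expect_equal(share, unname(p_oracle >= 0.05))
    }
  }
})

test_that("Tukey letters handle degenerate separations", {
  # all means equal: everything shares one letter
  tk <- tukey_letters(rep(c(1, 1, 1), each = 3) + rep(c(0, 0, 0), 3),
                      rep(1:3, each = 3))
  expect_true(all(tk$letters == "a"))
  # one extreme level with tiny variance gets its own letter
  v <- c(rnorm(3, 0, 1e-4), rnorm(3, 0, 1e-4), rnorm(3, 50, 1e-4))
  tk2 <- tukey_letters(v, rep(c("x", "y", "z"), each = 3))
  expect_equal(unname(tk2$letters["z"]), "a")      # highest mean, own letter
  expect_false(tk2$letters["x"] == tk2$letters["z"])
  expect_equal(unname(tk2$letters["x"]), unname(tk2$letters["y"]))
})

test_that("polynomial contrast vectors are orthonormal with linear part on centred levels", {
  C <- poly_contrast_vectors(c(18, 21, 23, 27, 29, 32))
  centred <- c(-7, -4, -2, 2, 4, 7)   # levels minus their mean, 25
  expect_equal(C[, "linear"], centred / sqrt(sum(centred^2)), tolerance = 1e-12)
  expect_equal(sum(C[, "linear"]), 0, tolerance = 1e-12)
  expect_equal(sum(C[, "quadratic"]), 0, tolerance = 1e-12)
  expect_equal(sum(C[, "linear"] * C[, "quadratic"]), 0, tolerance = 1e-12)
  # matches the classical construction for any spacing
  set.seed(31)
  for (i in 1:10) {
    lv <- sort(sample(seq(5, 60), 5))
    C1 <- poly_contrast_vectors(lv)
    C2 <- contr.poly(5, scores = lv)[, 1:2]
    expect_equal(abs(C1[, 1]), abs(C2[, 1]), tolerance = 1e-10)
    expect_equal(abs(C1[, 2]), abs(C2[, 2]), tolerance = 1e-10)
    expect_equal(sum(C1[, 1] * C1[, 2]), 0, tolerance = 1e-12)
  }
  # balanced equal spacing reproduces the integer tables up to scaling
  C3 <- poly_contrast_vectors(c(10, 20, 30))
  expect_equal(C3[, "linear"] / C3[1, "linear"], c(1, 0, -1))
  expect_equal(C3[, "quadratic"] / C3[1, "quadratic"], c(1, -2, 1))
})

test_that("polynomial contrasts detect trends on unequally spaced temperatures", {
  temps <- rep(c(18, 23, 27, 32), each = 4)
  # exactly linear means: quadratic estimate is 0
  v_lin <- 2 * temps
  pc <- polynomial_contrasts(v_lin, temps)
  expect_equal(pc$estimate[pc$contrast == "quadratic"], 0, tolerance = 1e-10)
  expect_lt(pc$p[pc$contrast == "linear"], 1e-10)
  # equal means: both estimates 0 with p = 1
  pc0 <- polynomial_contrasts(rep(3, 16), temps)
  expect_equal(pc0$estimate, c(0, 0))
  expect_equal(pc0$p, c(1, 1))
  expect_error(polynomial_contrasts(rnorm(8), rep(c(1, 2), each = 4)),
               "at least 3")
})

test_that("null linear-contrast p-values are uniform", {
  set.seed(2026)
  temps <- rep(c(18, 21, 23, 27, 29, 32), each = 6)
  ps <- replicate(400, {
    pc <- polynomial_contrasts(rnorm(36), temps)
    pc$p[pc$contrast == "linear"]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cross-treatment CV follows the sample-SD definition", {
  expect_equal(cv_across_treatments(c(1, 1, 1)), 0)
  m <- c(2.29, 2.28, 1.71, 1.22)
  expect_equal(cv_across_treatments(m), 100 * sd(m) / mean(m))
  expect_equal(cv_across_treatments(m), 27.41, tolerance = 1e-3)
  expect_equal(cv_across_treatments(3 * m), cv_across_treatments(m))
  expect_error(cv_across_treatments(c(-1, 1)), "undefined")
})

test_that("treatment summary assembles the balance-table columns", {
  tr <- simulate_trial(trial_design("toy", c(18, 25, 32), 4, 30, 1.5,
                                    n_balance_days = 2), seed = 12)
  led <- energy_ledger(tr)
  ts_ <- treatment_summary(led, "me_i")
  expect_equal(nrow(ts_$table), 3)
  expect_true(all(c("mean", "sem", "letter") %in% names(ts_$table)))
  expect_true(ts_$p_linear >= 0 && ts_$p_linear <= 1)
})
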