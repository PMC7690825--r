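# internal: validate a response/level pairing for treatment statistics
check_treatment_table <- function(value, level) {
  if (length(value) != length(level)) stop("value and level lengths differ")
  keep <- is.finite(value)
  value <- value[keep]; level <- level[keep]
  f <- factor(level)
  if (nlevels(f) < 2) stop("need at least two treatment levels")
  n <- table(f)
  if (any(n < 2))
    stop("variance error: level(s) ", paste(names(n)[n < 2], collapse = ", "),
         " have fewer than two animals")
  list(value = value, level = f, n = n)
}

#' One-way treatment ANOVA
#'
#' Classical between/within decomposition with ambient temperature (or any
#' single factor) as the only fixed effect. The per-level standard error of
#' the mean is `sqrt(MSE / n_level)`, the pooled form used in treatment
#' tables.
#'
#' @param value response vector (one value per animal).
#' @param level treatment level of each animal (coerced to factor).
#' @return list with `f`, `p`, `mse` (residual mean square), `df_between`,
#'   `df_within`, and `means` (data.frame: level, n, mean, sem).
#' @examples
#' anova_oneway(c(1, 2, 3, 5, 6, 7), rep(c("a", "b"), each = 3))
#' @export
anova_oneway <- function(value, level) {
  tt <- check_treatment_table(value, level)
  fit <- stats::aov(tt$value ~ tt$level)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  f <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
  if (stats::var(tt$value) <= 1e-20 * max(1, mean(tt$value)^2)) {
    # a constant response carries no treatment signal
    f <- 0; p <- 1; mse <- 0
  } else if (!is.finite(f)) { f <- 0; p <- 1 }
  means <- data.frame(
    level = levels(tt$level),
    n = as.integer(tt$n),
    mean = as.numeric(tapply(tt$value, tt$level, mean)),
    sem = sqrt(mse / as.integer(tt$n))
  )
  list(f = f, p = p, mse = mse,
       df_between = an[1, "Df"], df_within = an["Residuals", "Df"],
       means = means)
}

#' Tukey HSD separation with compact letters
#'
#' All-pairs Tukey honestly-significant-difference comparisons followed by a
#' compact letter display: working down from the highest mean, each level
#' joins every existing letter group with which it does not differ at
#' `alpha`, or opens a new letter. Two levels share a letter iff their Tukey
#' p-value is at least `alpha`.
#'
#' @param value,level as in [anova_oneway()].
#' @param alpha significance level for letter separation.
#' @return list with `p_matrix` (symmetric matrix of Tukey p-values) and
#'   `letters` (named character vector, levels in input order).
#' @examples
#' tukey_letters(c(1, 1.1, 0.9, 5, 5.2, 4.9), rep(c("lo", "hi"), each = 3))
#' @export
tukey_letters <- function(value, level, alpha = 0.05) {
  tt <- check_treatment_table(value, level)
  fit <- stats::aov(tt$value ~ tt$level)
  lv <- levels(tt$level)
  k <- length(lv)
  pm <- matrix(1, k, k, dimnames = list(lv, lv))
  if (stats::deviance(fit) > 0) {
    thsd <- stats::TukeyHSD(fit)[[1]]
    pairs <- strsplit(rownames(thsd), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]; b <- pairs[[i]][2]
      pm[a, b] <- pm[b, a] <- thsd[i, "p adj"]
    }
  } else {
    # zero residual variance: any mean difference is a sure separation
    mns <- tapply(tt$value, tt$level, mean)
    for (a in lv) for (b in lv)
      if (a != b && abs(mns[a] - mns[b]) > 0) pm[a, b] <- 0
  }
  # letters = maximal cliques of the "not separated" graph, so that two
  # levels share a letter iff their Tukey p >= alpha; cliques are lettered
  # from the one containing the highest mean downwards
  adj <- pm >= alpha
  diag(adj) <- TRUE
  subsets <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(k, sz, simplify = FALSE)), recursive = FALSE)
  is_clique <- vapply(subsets, function(s) all(adj[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    s <- cliques[[i]]
    !any(vapply(cliques, function(t2)
      length(t2) > length(s) && all(s %in% t2), logical(1)))
  }, logical(1))
  groups <- cliques[maximal]
  mns <- tapply(tt$value, tt$level, mean)
  groups <- groups[order(-vapply(groups, function(s) max(mns[s]), numeric(1)))]
  letter_of <- stats::setNames(rep("", k), lv)
  for (gi in seq_along(groups))
    for (x in lv[groups[[gi]]])
      letter_of[x] <- paste0(letter_of[x], letters[gi])
  list(p_matrix = pm, letters = letter_of)
}

#' Orthogonal polynomial contrast vectors for arbitrary level spacings
#'
#' Gram-Schmidt orthogonalisation of `(1, t, t^2)` over the actual
#' (possibly unequally spaced) level values, optionally weighted by group
#' sizes, normalised to unit length. The linear vector is proportional to
#' the centred levels; the quadratic vector is orthogonal to both the
#' constant and the linear vector.
#'
#' @param levels numeric treatment levels (distinct, >= 2; >= 3 for a
#'   quadratic vector).
#' @param weights optional nonnegative weights (group sizes); equal weights
#'   give the classical unweighted contrasts.
#' @return matrix with columns `linear` and (when possible) `quadratic`.
#' @examples
#' poly_contrast_vectors(c(18, 21, 23, 27, 29, 32))
#' @export
poly_contrast_vectors <- function(levels, weights = NULL) {
  k <- length(levels)
  if (k < 2 || anyDuplicated(levels)) stop("need >= 2 distinct levels")
  if (is.null(weights)) weights <- rep(1, k)
  stopifnot(length(weights) == k, all(weights > 0))
  w <- weights / sum(weights)
  ip <- function(u, v) sum(w * u * v)
  basis <- list(rep(1, k), levels)
  if (k >= 3) basis[[3]] <- levels^2
  out <- list()
  ortho <- list()
  for (j in seq_along(basis)) {
    v <- basis[[j]]
    for (u in ortho) v <- v - ip(v, u) / ip(u, u) * u
    ortho[[j]] <- v
    if (j > 1) out[[j - 1]] <- v / sqrt(sum(v^2))
  }
  m <- do.call(cbind, out)
  colnames(m) <- c("linear", "quadratic")[seq_len(ncol(m))]
  m
}

#' Polynomial contrasts on treatment means
#'
#' Tests the linear and quadratic trends of the level means over the actual
#' temperature values. Contrast vectors come from [stats::contr.poly()] with
#' the levels as scores when the design is balanced (the classical
#' unweighted construction) and from weighted Gram-Schmidt otherwise; the
#' t-test uses the one-way-ANOVA residual mean square.
#'
#' @param value,level as in [anova_oneway()]; `level` must be numeric (the
#'   temperatures).
#' @return data.frame with one row per contrast (`linear`, `quadratic`):
#'   `estimate`, `se`, `t`, `p`, plus the contrast matrix as attribute
#'   `vectors`.
#' @examples
#' temps <- rep(c(18, 23, 27, 32), each = 3)
#' polynomial_contrasts(temps * 0.1 + rnorm(12, 0, 0.01), temps)
#' @export
polynomial_contrasts <- function(value, level) {
  if (!is.numeric(level)) stop("levels must be numeric for polynomial contrasts")
  tt <- check_treatment_table(value, level)
  lv_num <- as.numeric(levels(tt$level))
  k <- length(lv_num)
  if (k < 3)
    stop("contrast error: need at least 3 distinct levels for a quadratic trend")
  n <- as.integer(tt$n)
  balanced <- length(unique(n)) == 1
  C <- if (balanced) {
    cp <- stats::contr.poly(k, scores = lv_num)[, 1:2, drop = FALSE]
    colnames(cp) <- c("linear", "quadratic")
    cp
  } else {
    poly_contrast_vectors(lv_num, weights = n)
  }
  an <- anova_oneway(tt$value, tt$level)
  mns <- an$means$mean
  df <- an$df_within
  out <- lapply(colnames(C), function(nm) {
    cv <- C[, nm]
    est <- sum(cv * mns)
    se <- sqrt(an$mse * sum(cv^2 / n))
    null_est <- abs(est) <= 1e-10 * max(1, max(abs(mns)))
    tv <- if (se > 0) est / se else if (null_est) 0 else Inf
    data.frame(contrast = nm, estimate = est, se = se, t = tv,
               p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "vectors") <- C
  res
}

#' Coefficient of variation across treatment means
#'
#' Percent CV of the per-treatment means (sample SD over mean), used to
#' compare the temperature sensitivity of a response between trials.
#'
#' @param level_means vector of treatment-level means (>= 2, nonzero mean).
#' @return CV in percent.
#' @examples
#' cv_across_treatments(c(2.29, 2.28, 1.71, 1.22))
#' @export
cv_across_treatments <- function(level_means) {
  if (length(level_means) < 2) stop("need at least two level means")
  m <- mean(level_means)
  if (m == 0) stop("CV undefined: mean of level means is zero")
  100 * stats::sd(level_means) / m
}

#' Treatment summary in the balance-table layout
#'
#' One-stop treatment report for a response of the energy ledger: level
#' means with Tukey letters, pooled SEM, the ANOVA p-value and the linear
#' and quadratic polynomial-contrast p-values -- the column layout of a
#' nitrogen/energy balance table.
#'
#' @param data data.frame with the response column and a numeric `temp_C`
#'   column.
#' @param response name of the response column.
#' @param alpha letter-separation level.
#' @return list with `table` (level, n, mean, sem, letter), `p_anova`,
#'   `p_linear`, `p_quadratic`.
#' @examples
#' tr <- simulate_trial(trial_design("toy", c(18, 25, 32), 3, 30, 1), seed = 2)
#' led <- energy_ledger(tr)
#' treatment_summary(led, "thp")$table
#' @export
treatment_summary <- function(data, response, alpha = 0.05) {
  stopifnot(response %in% names(data), "temp_C" %in% names(data))
  v <- data[[response]]; lv <- data$temp_C
  an <- anova_oneway(v, lv)
  tk <- tukey_letters(v, lv, alpha = alpha)
  pc <- polynomial_contrasts(v, lv)
  tab <- an$means
  tab$letter <- tk$letters[tab$level]
  list(table = tab, p_anova = an$p,
       p_linear = pc$p[pc$contrast == "linear"],
       p_quadratic = pc$p[pc$contrast == "quadratic"])
}
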