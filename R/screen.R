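# internal: accept either a feature_table or (matrix, group)
as_feature_matrix <- function(x, group = NULL) {
  if (inherits(x, "feature_table")) return(list(x = x$x, group = x$group))
  if (is.null(group)) stop("group labels required with a plain matrix")
  list(x = as.matrix(x), group = factor(group, levels = c("low", "neutral", "high")))
}

#' Pareto scaling
#'
#' Per-feature normalisation intermediate between mean-centering and
#' unit-variance scaling: subtract the feature mean and divide by the square
#' root of its standard deviation. A zero-variance feature maps to all
#' zeros. Column-wise over a samples-by-features matrix.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @return scaled matrix of the same shape.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
#' pareto_scale(m)
#' @export
pareto_scale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two samples")
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  out <- sweep(x, 2, mu)
  nz <- s > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sqrt(s[nz]), `/`)
  out[, !nz] <- 0
  out
}

#' Pairwise group fold changes
#'
#' Ratios of group-mean raw intensities per feature for the three standard
#' comparisons of a low/neutral/high temperature design: high/neutral,
#' low/neutral and high/low. A fold change above 1 marks an up-regulated
#' feature in the comparison's numerator group.
#'
#' @param x samples-by-features intensity matrix (raw, nonnegative) or a
#'   `feature_table`.
#' @param group sample group labels (`low`, `neutral`, `high`); ignored if
#'   `x` is a `feature_table`.
#' @return data.frame with `feature`, `fc_high_neutral`, `fc_low_neutral`,
#'   `fc_high_low` (NA where a denominator group mean is zero).
#' @examples
#' ft <- simulate_feature_table(4, 5, seed = 3)
#' fold_changes(ft)
#' @export
fold_changes <- function(x, group = NULL) {
  fm <- as_feature_matrix(x, group)
  gm <- rowsum(fm$x, fm$group) / as.vector(table(fm$group))
  ratio <- function(a, b) {
    r <- gm[a, ] / gm[b, ]
    r[gm[b, ] <= 0] <- NA_real_
    r
  }
  data.frame(
    feature = colnames(fm$x) %||% seq_len(ncol(fm$x)),
    fc_high_neutral = ratio("high", "neutral"),
    fc_low_neutral = ratio("low", "neutral"),
    fc_high_low = ratio("high", "low"),
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Differential-metabolite screening rule
#'
#' The conjunction rule for selecting differential features from a
#' three-group (low/neutral/high ambient temperature) plasma feature table:
#' a feature is selected iff (i) at least one pairwise fold change exceeds
#' `fc_threshold` in either direction (FC > threshold or FC < 1/threshold),
#' (ii) its maximum within-group CV of raw intensities is below
#' `cv_threshold` percent, and (iii) its one-way ANOVA p-value across the
#' three groups, computed on Pareto-scaled intensities, is below
#' `p_threshold`. No multiple-testing correction is applied. Results are
#' ordered by p-value, ties broken by descending maximum absolute log2 fold
#' change.
#'
#' @param x samples-by-features raw intensity matrix or a `feature_table`.
#' @param group sample group labels; ignored for a `feature_table`.
#' @param fc_threshold fold-change gate (default 1.5).
#' @param cv_threshold within-group CV gate, percent (default 20).
#' @param p_threshold ANOVA p gate (default 0.05).
#' @return data.frame, one row per feature (screening order): fold-change
#'   triplet, `cv_max_pct`, `p`, `selected`, and `direction` of the
#'   high-vs-low comparison (`up`, `down` or `flat`).
#' @examples
#' ft <- simulate_feature_table(6, 40,
#'         planted = data.frame(feature = 1:2, fc_high = 4, fc_low = 1),
#'         seed = 5)
#' head(screen_features(ft), 3)
#' @export
screen_features <- function(x, group = NULL, fc_threshold = 1.5,
                            cv_threshold = 20, p_threshold = 0.05) {
  fm <- as_feature_matrix(x, group)
  if (nlevels(droplevels(fm$group)) < 2)
    stop("screen error: need at least two groups")
  if (fc_threshold < 1) stop("fold-change threshold must be >= 1")
  fc <- fold_changes(fm$x, fm$group)

  scaled <- pareto_scale(fm$x)
  pvals <- apply(scaled, 2, function(v) {
    if (stats::sd(v) == 0) return(1)
    an <- stats::anova(stats::lm(v ~ fm$group))
    an[1, "Pr(>F)"]
  })

  cv_by_group <- sapply(levels(fm$group), function(g) {
    sub <- fm$x[fm$group == g, , drop = FALSE]
    100 * apply(sub, 2, stats::sd) / colMeans(sub)
  })
  cv_max <- apply(cv_by_group, 1, max)

  fc_cols <- as.matrix(fc[, c("fc_high_neutral", "fc_low_neutral", "fc_high_low")])
  fc_pass <- apply(fc_cols, 1, function(r) {
    r <- r[is.finite(r)]
    length(r) > 0 && any(r > fc_threshold | r < 1 / fc_threshold)
  })
  max_abs_l2fc <- apply(fc_cols, 1, function(r) {
    r <- r[is.finite(r) & r > 0]
    if (!length(r)) return(0)
    max(abs(log2(r)))
  })

  out <- data.frame(
    feature = fc$feature,
    fc_high_neutral = fc$fc_high_neutral,
    fc_low_neutral = fc$fc_low_neutral,
    fc_high_low = fc$fc_high_low,
    cv_max_pct = cv_max,
    p = pvals,
    selected = fc_pass & cv_max < cv_threshold & pvals < p_threshold,
    direction = ifelse(!is.finite(fc$fc_high_low), "flat",
                       ifelse(fc$fc_high_low > 1, "up",
                              ifelse(fc$fc_high_low < 1, "down", "flat"))),
    row.names = NULL
  )
  out[order(out$p, -max_abs_l2fc), ]
}

#' PCA quality report for a feature table
#'
#' Principal-component decomposition of the Pareto-scaled intensity matrix,
#' reported as explained-variance fractions -- a quick check that group
#' structure, not batch noise, dominates the table.
#'
#' @param x samples-by-features matrix or `feature_table`.
#' @param group ignored for a `feature_table`.
#' @param n_components number of components to report.
#' @return data.frame with `component`, `variance_fraction` and `scores`
#'   attribute (samples x components).
#' @examples
#' ft <- simulate_feature_table(4, 20, seed = 4)
#' screen_pca(ft)
#' @export
screen_pca <- function(x, group = NULL, n_components = 5) {
  fm <- as_feature_matrix(x, group)
  pc <- stats::prcomp(pareto_scale(fm$x), center = FALSE, scale. = FALSE)
  k <- min(n_components, length(pc$sdev))
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  out <- data.frame(component = seq_len(k), variance_fraction = vf[seq_len(k)])
  attr(out, "scores") <- pc$x[, seq_len(k), drop = FALSE]
  out
}
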