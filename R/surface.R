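#' Published response-surface coefficients for modern growing pigs
#'
#' Coefficient sets of the quadratic bodyweight-by-temperature response
#' surfaces reported for modern growing pigs between 18 and 32 degC:
#' voluntary feed intake (`vfi`, kg/d), metabolizable energy intake (`mei`,
#' kJ/kg BW^0.6/d), and energy retention as protein (`re_p`) and lipid
#' (`re_l`, both kJ/kg BW^0.6/d, with ME intake as an additional covariate).
#' Each surface has terms
#' `a + b*BW^0.6 + c*(BW^0.6)^2 + d*T + e*T^2 + f*BW^0.6*T [+ g*ME_i]`.
#' The attached `rmse` attribute carries the reported residual errors, used
#' by the simulator to set realistic noise levels.
#'
#' These serve as the generator's default ground truth; they are inputs, not
#' estimates produced by this package.
#'
#' @return named list of coefficient vectors with attribute `rmse`.
#' @examples
#' pig_surface_coefficients()$vfi
#' @export
pig_surface_coefficients <- function() {
  out <- list(
    vfi  = c(a = -7.72, b = 1.54, c = -0.059, d = 0.15, e = -0.0022,
             f = -0.0088),
    mei  = c(a = -9242.45, b = 2042.05, c = -91.95, d = 242.32, e = -4.56,
             f = -8.33),
    re_p = c(a = -233.38, b = -67.28, c = 3.16, d = 39.58, e = -0.76,
             f = -0.26, g = 0.26),
    re_l = c(a = -465.10, b = 8.10, c = -1.03, d = -53.73, e = 1.34,
             f = 0.67, g = 0.69)
  )
  attr(out, "rmse") <- c(vfi = 0.18, mei = 316.30, re_p = 61.66, re_l = 134.58)
  out
}

#' Evaluate a bodyweight-by-temperature response surface
#'
#' Exact polynomial evaluation of
#' `a + b*m + c*m^2 + d*T + e*T^2 + f*m*T (+ g*ME_i)` with `m = BW^0.6`.
#' The `g` term is applied iff the coefficient vector contains `g`, in which
#' case `me_i` must be supplied.
#'
#' @param coeffs named coefficients (`a`..`f`, optionally `g`).
#' @param bw_kg bodyweight, kg (positive).
#' @param temp_C ambient temperature, degC.
#' @param me_i metabolizable energy intake (kJ/kg BW^0.6/d), required iff
#'   `coeffs` has a `g` term.
#' @return predicted response (units of the surface).
#' @examples
#' evaluate_surface(pig_surface_coefficients()$vfi, 28.7, 18)
#' @export
evaluate_surface <- function(coeffs, bw_kg, temp_C, me_i = NULL) {
  need <- c("a", "b", "c", "d", "e", "f")
  if (!all(need %in% names(coeffs)))
    stop("coefficients must be named a..f (optionally g)")
  if (any(bw_kg <= 0)) stop("bodyweight must be positive")
  m <- bw_kg^0.6
  y <- coeffs[["a"]] + coeffs[["b"]] * m + coeffs[["c"]] * m^2 +
    coeffs[["d"]] * temp_C + coeffs[["e"]] * temp_C^2 +
    coeffs[["f"]] * m * temp_C
  if ("g" %in% names(coeffs)) {
    if (is.null(me_i))
      stop("argument error: this surface has a g term and needs me_i")
    y <- y + coeffs[["g"]] * me_i
  }
  y
}

#' Gauss-Newton nonlinear least squares
#'
#' Minimises `sum((y - f(theta))^2)` by Gauss-Newton iteration: at each step
#' the update solves the linearised normal equations through a QR
#' factorisation of the Jacobian. For models linear in their parameters the
#' first step lands on the least-squares solution exactly. Convergence is
#' declared when the gradient norm `||J'r||` falls below `tol` (scaled by
#' the residual norm).
#'
#' @param residual_fn function(theta) returning the residual vector
#'   `y - f(theta)`.
#' @param jacobian_fn function(theta) returning the Jacobian of `f` (n x p).
#' @param init starting parameter vector.
#' @param tol relative step-size tolerance: convergence is declared when the
#'   proposed update is below `tol` relative to the current parameter norm
#'   (a scale-invariant criterion; the gradient norm is also reported).
#' @param max_iter iteration cap.
#' @return list with `par`, `rss`, `iterations`, `converged`,
#'   `gradient_norm`.
#' @examples
#' x <- 1:10; y <- 2 + 3 * x
#' fit <- gauss_newton(function(b) y - (b[1] + b[2] * x),
#'                     function(b) cbind(1, x), c(0, 0))
#' fit$par
#' @export
gauss_newton <- function(residual_fn, jacobian_fn, init, tol = 1e-10,
                         max_iter = 100) {
  theta <- init
  converged <- FALSE
  steps <- 0
  grad_norm <- NA_real_
  repeat {
    r <- residual_fn(theta)
    J <- jacobian_fn(theta)
    qrJ <- qr(J)
    if (qrJ$rank < ncol(J)) {
      pivot_bad <- qrJ$pivot[(qrJ$rank + 1):ncol(J)]
      nm <- colnames(J)[pivot_bad]
      stop("fit error: rank-deficient design; collinear term(s): ",
           paste(if (is.null(nm)) pivot_bad else nm, collapse = ", "))
    }
    grad_norm <- sqrt(sum(crossprod(J, r)^2))
    delta <- qr.coef(qrJ, r)
    if (sqrt(sum(delta^2)) <= tol * (sqrt(sum(theta^2)) + tol)) {
      converged <- TRUE; break
    }
    if (steps >= max_iter) break
    theta <- theta + delta
    steps <- steps + 1
  }
  list(par = theta, rss = sum(residual_fn(theta)^2), iterations = steps,
       converged = converged, gradient_norm = grad_norm)
}

# internal: design matrix of the surface terms
surface_design_matrix <- function(bw_kg, temp_C, me_i = NULL, has_g = FALSE) {
  m <- bw_kg^0.6
  X <- cbind(a = 1, b = m, c = m^2, d = temp_C, e = temp_C^2, f = m * temp_C)
  if (has_g) {
    if (is.null(me_i)) stop("argument error: surface with g term needs me_i")
    X <- cbind(X, g = me_i)
  }
  X
}

#' Fit a bodyweight-by-temperature response surface
#'
#' Fits one of the four quadratic response surfaces (voluntary feed intake,
#' ME intake, protein retention, lipid retention) to pooled per-animal trial
#' data by Gauss-Newton least squares. The protein/lipid-retention surfaces
#' include ME intake as a covariate (`g` term); the intake surfaces do not.
#'
#' @param data data.frame with columns `bw_kg`, `temp_C`, the response named
#'   in `response`, and `me_i` when the surface has a `g` term.
#' @param response one of `"vfi"`, `"mei"`, `"re_p"`, `"re_l"`, naming both
#'   the response column and the surface form.
#' @param init starting coefficients (default all zero).
#' @param tol,max_iter passed to [gauss_newton()].
#' @return object of class `surface_fit`: coefficients `a`..`f` (and `g`),
#'   `rmse` (`sqrt(RSS/(n-p))`), `r2`, `sigma` covariance-based standard
#'   errors, overall F-test p-value, `n_obs`, `converged`, `iterations`.
#' @seealso [predict.surface_fit()], [surface_report()]
#' @examples
#' d <- simulate_surface_responses(seed = 1)
#' fit <- fit_response_surface(d, "vfi")
#' coef(fit)
#' @export
fit_response_surface <- function(data, response = c("vfi", "mei", "re_p", "re_l"),
                                 init = NULL, tol = 1e-10, max_iter = 100) {
  response <- match.arg(response)
  has_g <- response %in% c("re_p", "re_l")
  need <- c("bw_kg", "temp_C", response, if (has_g) "me_i")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("data is missing column(s): ", paste(missing, collapse = ", "))
  y <- data[[response]]
  X <- surface_design_matrix(data$bw_kg, data$temp_C,
                             if (has_g) data$me_i, has_g)
  p <- ncol(X)
  if (nrow(X) <= p)
    stop("need more observations than coefficients (", p, ")")
  if (is.null(init)) init <- stats::setNames(rep(0, p), colnames(X))

  gn <- gauss_newton(function(th) y - drop(X %*% th),
                     function(th) X, init, tol = tol, max_iter = max_iter)
  theta <- stats::setNames(gn$par, colnames(X))
  fitted <- drop(X %*% theta)
  rss <- gn$rss
  tss <- sum((y - mean(y))^2)
  df_res <- length(y) - p
  rmse <- sqrt(rss / df_res)
  r2 <- 1 - rss / tss
  # overall F test against the intercept-only model
  f_stat <- ((tss - rss) / (p - 1)) / (rss / df_res)
  p_value <- stats::pf(f_stat, p - 1, df_res, lower.tail = FALSE)
  XtXi <- chol2inv(qr.R(qr(X)))
  se <- stats::setNames(sqrt(diag(XtXi)) * rmse, colnames(X))
  if (!gn$converged)
    warning("Gauss-Newton did not converge; returning the last iterate")
  structure(list(
    response = response, coefficients = theta, se = se,
    fitted.values = fitted, residuals = y - fitted,
    rmse = rmse, r2 = r2, f_statistic = f_stat, p_value = p_value,
    n_obs = length(y), df_residual = df_res,
    converged = gn$converged, iterations = gn$iterations,
    gradient_norm = gn$gradient_norm, has_g = has_g,
    call = match.call()
  ), class = "surface_fit")
}

#' @export
coef.surface_fit <- function(object, ...) object$coefficients

#' @export
residuals.surface_fit <- function(object, ...) object$residuals

#' @export
fitted.surface_fit <- function(object, ...) object$fitted.values

#' Predict from a fitted response surface
#'
#' @param object a `surface_fit`.
#' @param newdata data.frame with `bw_kg`, `temp_C` (and `me_i` for
#'   retention surfaces); omitted for fitted values.
#' @param ... unused.
#' @return predicted responses.
#' @export
predict.surface_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- surface_design_matrix(newdata$bw_kg, newdata$temp_C,
                             newdata$me_i, object$has_g)
  drop(X %*% object$coefficients)
}

#' @export
print.surface_fit <- function(x, digits = 4, ...) {
  cat("Response surface fit:", toupper(x$response),
      "~ BW^0.6 x temperature", if (x$has_g) "+ ME intake", "\n")
  print(round(x$coefficients, digits))
  cat("RMSE ", signif(x$rmse, digits), ", R^2 ", signif(x$r2, 3),
      ", n = ", x$n_obs, ", ", x$iterations, " Gauss-Newton iteration(s)",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.surface_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$coefficients / object$se)
  tab <- cbind(tab, `Pr(>|t|)` = 2 * stats::pt(abs(tab[, "t value"]),
                                               object$df_residual,
                                               lower.tail = FALSE))
  structure(list(response = object$response, coefficients = tab,
                 rmse = object$rmse, r2 = object$r2,
                 f_statistic = object$f_statistic, p_value = object$p_value,
                 n_obs = object$n_obs, converged = object$converged),
            class = "summary.surface_fit")
}

#' @export
print.summary.surface_fit <- function(x, ...) {
  cat("Response surface:", toupper(x$response), "\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("RMSE ", signif(x$rmse, 4), ", R^2 ", signif(x$r2, 3),
      ", overall F p = ", format.pval(x$p_value), ", n = ", x$n_obs, "\n",
      sep = "")
  invisible(x)
}

#' Tabulate fitted response surfaces
#'
#' Assemble fitted surfaces into the customary report layout: one row per
#' model with coefficients `a`..`g` (a `"/"` placeholder where a surface has
#' no `g` term), RMSE, R-squared and the overall F-test p-value.
#'
#' @param fits a list of `surface_fit` objects (at least one).
#' @return data.frame, one row per fit.
#' @examples
#' d <- simulate_surface_responses(seed = 1)
#' surface_report(list(fit_response_surface(d, "vfi")))
#' @export
surface_report <- function(fits) {
  if (length(fits) == 0) stop("need at least one fit")
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "surface_fit"))
    cf <- f$coefficients
    fmt <- function(nm) if (nm %in% names(cf)) format(signif(cf[[nm]], 6)) else "/"
    data.frame(
      response = toupper(f$response),
      a = fmt("a"), b = fmt("b"), c = fmt("c"), d = fmt("d"), e = fmt("e"),
      f = fmt("f"), g = fmt("g"),
      rmse = f$rmse, r2 = f$r2, p_value = f$p_value
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate per-animal responses from the pooled two-stage design
#'
#' Draws the pooled two-trial design (six temperatures x six replicates at
#' the 25-kg stage, four temperatures x six replicates at the 65-kg stage;
#' average bodyweights around 28.7 and 69 kg) and generates the four surface
#' responses from given ground-truth coefficients plus Gaussian noise. The
#' protein/lipid-retention responses use the noisy realised ME intake as
#' their covariate, as a real analysis would. Noise SDs default to the
#' reported residual errors of the published surfaces, which puts the
#' intake-surface R-squared near 0.85.
#'
#' @param coefficients list of generating coefficient vectors, as
#'   [pig_surface_coefficients()].
#' @param noise_sd named vector of residual SDs for `vfi`, `mei`, `re_p`,
#'   `re_l`; `0` for noiseless data.
#' @param n_reps replicates per temperature.
#' @param temps_stage1,temps_stage2 temperature sets of the two stages.
#' @param bw_mean,bw_sd length-2 vectors: average-bodyweight distribution of
#'   the two stages, kg.
#' @param seed integer seed (local to this call).
#' @return data.frame with `stage`, `bw_kg`, `temp_C`, `vfi`, `mei`, `me_i`
#'   (alias of `mei`, the covariate used by the retention surfaces), `re_p`,
#'   `re_l`; the generating coefficients are attached as attribute `truth`.
#' @examples
#' d <- simulate_surface_responses(noise_sd = c(vfi = 0, mei = 0, re_p = 0,
#'                                              re_l = 0), seed = 1)
#' nrow(d)
#' @export
simulate_surface_responses <- function(coefficients = pig_surface_coefficients(),
                                       noise_sd = attr(pig_surface_coefficients(), "rmse"),
                                       n_reps = 6,
                                       temps_stage1 = c(18, 21, 23, 27, 29, 32),
                                       temps_stage2 = c(18, 23, 27, 32),
                                       bw_mean = c(28.7, 69), bw_sd = c(2.0, 2.5),
                                       seed = NULL) {
  if (length(noise_sd) == 1) noise_sd <- stats::setNames(
    rep(noise_sd, 4), c("vfi", "mei", "re_p", "re_l"))
  with_seed(seed, {
    temp <- c(rep(temps_stage1, each = n_reps), rep(temps_stage2, each = n_reps))
    stage <- rep(c("25kg", "65kg"),
                 c(length(temps_stage1), length(temps_stage2)) * n_reps)
    bw <- c(stats::rnorm(length(temps_stage1) * n_reps, bw_mean[1], bw_sd[1]),
            stats::rnorm(length(temps_stage2) * n_reps, bw_mean[2], bw_sd[2]))
    bw <- pmax(bw, 5)
    n <- length(bw)
    mei <- evaluate_surface(coefficients$mei, bw, temp) +
      stats::rnorm(n, 0, noise_sd[["mei"]])
    vfi <- evaluate_surface(coefficients$vfi, bw, temp) +
      stats::rnorm(n, 0, noise_sd[["vfi"]])
    re_p <- evaluate_surface(coefficients$re_p, bw, temp, me_i = mei) +
      stats::rnorm(n, 0, noise_sd[["re_p"]])
    re_l <- evaluate_surface(coefficients$re_l, bw, temp, me_i = mei) +
      stats::rnorm(n, 0, noise_sd[["re_l"]])
    out <- data.frame(stage = stage, bw_kg = bw, temp_C = temp,
                      vfi = vfi, mei = mei, me_i = mei,
                      re_p = re_p, re_l = re_l)
    attr(out, "truth") <- coefficients
    out
  })
}
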