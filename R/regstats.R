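#' Single-population sample-size formula
#'
#' `N = P (1 - P) Z^2 / d^2`, rounded to the nearest integer: the standard
#' single population proportion estimate used to plan a cross-sectional
#' study.  With unknown prevalence (`P = 0.5`), 95% confidence
#' (`Z = 1.96`) and a 5% margin (`d = 0.05`) the formula gives 384.
#'
#' @param P Prevalence in \[0, 1\].
#' @param Z Standard-normal quantile for the confidence level.
#' @param d Margin of error in (0, 1\].
#' @return Integer sample size.
#' @examples
#' sample_size(0.5, 1.96, 0.05)  # 384
#' @export
sample_size <- function(P, Z, d) {
  stopifnot(is.finite(P), is.finite(Z), is.finite(d))
  if (P < 0 || P > 1) stop("'P' must be in [0, 1]")
  if (d <= 0) stop("'d' must be > 0")
  as.integer(round(P * (1 - P) * Z^2 / d^2))
}

#' Screen candidate predictors by Pearson correlation
#'
#' Ranks candidate predictors by the absolute Pearson correlation with the
#' target and selects those with `|r| >= threshold` and `p <= alpha`
#' (two-sided t-test).  Constant candidates have undefined correlation and
#' are reported with status `"undefined"` and never selected.
#'
#' @param data A data.frame of numeric columns.
#' @param target Name of the outcome column.
#' @param candidates Candidate column names (default: all except target).
#' @param threshold Minimum `|r|` for selection (default 0.3).
#' @param alpha Significance level (default 0.05).
#' @return A data.frame with one row per candidate, ordered by decreasing
#'   `|r|`: columns `predictor`, `r`, `p`, `n`, `status`
#'   (selected/rejected/undefined).
#' @export
pearson_select <- function(data, target, candidates = NULL,
                           threshold = 0.3, alpha = 0.05) {
  if (!target %in% names(data)) stop("target column not found: ", target)
  if (is.null(candidates)) candidates <- setdiff(names(data), target)
  y <- data[[target]]
  rows <- lapply(candidates, function(nm) {
    x <- data[[nm]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3L) stop("fewer than 3 complete cases for candidate ", nm)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(predictor = nm, r = NA_real_, p = NA_real_, n = n,
                        status = "undefined"))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(predictor = nm, r = unname(ct$estimate),
               p = ct$p.value, n = n,
               status = if (abs(ct$estimate) >= threshold &&
                            ct$p.value <= alpha) "selected" else "rejected")
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$r), na.last = TRUE), , drop = FALSE]
}

#' Ordinary least-squares fit with the full diagnostic tables
#'
#' Fits `y ~ X` with an intercept and returns the complete
#' model-development report: per-predictor unstandardised and standardised
#' coefficients, standard errors, t and p, 95% confidence bounds,
#' collinearity tolerance and VIF; the model summary (R, R-squared,
#' adjusted R-squared, standard error of the estimate, Durbin-Watson); the
#' ANOVA decomposition; and the residual vector.  Rows with missing values
#' are dropped listwise, with the count recorded in `n_dropped`.
#'
#' @param X A data.frame or matrix of numeric predictors (named columns).
#' @param y Numeric outcome (grams in the birth-weight application).
#' @param conf_level Confidence level for the coefficient intervals.
#' @return A `fitted_model` list with elements `model` (a
#'   [linear_model()]), `coefficients` (data.frame), `summary` (list),
#'   `anova` (an `anova_table`), `residuals`, `fitted`, `n`, `n_dropped`.
#' @examples
#' set.seed(1)
#' x <- data.frame(a = rnorm(50), b = rnorm(50))
#' fit_mlr(x, 2 + 3 * x$a - x$b + rnorm(50, sd = 0.1))$summary$r_square
#' @export
fit_mlr <- function(X, y, conf_level = 0.95) {
  X <- as.data.frame(X)
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all predictors must be numeric")
  k <- ncol(X)
  ok <- stats::complete.cases(X, y)
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X)
  if (n <= k + 1L) stop("need n > k + 1 observations")
  if (any(vapply(X, function(c) stats::sd(c) == 0, logical(1))))
    stop("constant predictor column")
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < k + 1L) {
    drop_idx <- qrX$pivot[seq.int(qrX$rank + 1L, k + 1L)] - 1L
    stop("rank-deficient design; collinear predictor set includes: ",
         paste(names(X)[drop_idx], collapse = ", "))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  lmfit <- stats::lm(.y ~ ., data = df)
  sm <- suppressWarnings(summary(lmfit)) # exact interpolation is legitimate
  B <- stats::coef(lmfit)
  SE <- sm$coefficients[, "Std. Error"]
  tval <- sm$coefficients[, "t value"]
  pval <- sm$coefficients[, "Pr(>|t|)"]
  dfres <- lmfit$df.residual
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, dfres)
  beta_std <- c(NA_real_, B[-1] * vapply(X, stats::sd, numeric(1)) / stats::sd(y))
  coll <- if (k >= 2L) collinearity_stats(X)
          else data.frame(predictor = names(X), tolerance = NA_real_,
                          vif = NA_real_)
  coefs <- data.frame(
    term = c("(constant)", names(X)),
    B = unname(B), std_error = unname(SE),
    beta = unname(beta_std), t = unname(tval), p = unname(pval),
    ci_lower = unname(B - tcrit * SE), ci_upper = unname(B + tcrit * SE),
    tolerance = c(NA_real_, coll$tolerance), vif = c(NA_real_, coll$vif))
  res <- stats::residuals(lmfit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  an <- anova_from_ss(ss_tot - ss_res, k, ss_res, dfres)
  structure(list(
    model = linear_model("fit_mlr", unname(B[1]),
                         stats::setNames(unname(B[-1]), names(X))),
    coefficients = coefs,
    summary = c(an$summary, list(durbin_watson = durbin_watson(res))),
    anova = an$anova, residuals = unname(res),
    fitted = unname(stats::fitted(lmfit)), n = n, n_dropped = n_dropped),
    class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  s <- x$summary
  cat(sprintf("fitted_model: n = %d, R = %.3f, R2 = %.3f, adj R2 = %.3f,\n",
              x$n, s$r, s$r_square, s$adj_r_square))
  cat(sprintf("  std error of estimate = %.3f, Durbin-Watson = %.3f\n",
              s$std_error_estimate, s$durbin_watson))
  cat(sprintf("  ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df_regression, x$anova$df_residual, x$anova$F,
              x$anova$p))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' ANOVA table and model summary from sums of squares
#'
#' Reconstructs the regression ANOVA table and the derived model-summary
#' statistics from the regression and residual sums of squares and degrees
#' of freedom alone: mean squares, the F ratio and its p-value,
#' R-squared (`SS_reg / SS_total`), R, adjusted R-squared and the standard
#' error of the estimate (`sqrt(MS_res)`).  This is exactly the arithmetic
#' linking a published ANOVA table to its model-summary table, so printed
#' tables can be checked for internal consistency.
#'
#' @param ss_regression,ss_residual Sums of squares (>= 0).
#' @param df_regression,df_residual Degrees of freedom (> 0).
#' @return List with `anova` (an `anova_table` list: ss/df/ms for each
#'   source, `F`, `p`) and `summary` (list: `r`, `r_square`,
#'   `adj_r_square`, `std_error_estimate`, `p`).
#' @examples
#' anova_from_ss(46427291.254, 4, 46138958.75, 379)$anova$F  # 95.342
#' @export
anova_from_ss <- function(ss_regression, df_regression,
                          ss_residual, df_residual) {
  if (df_regression <= 0 || df_residual <= 0)
    stop("degrees of freedom must be positive")
  if (ss_regression < 0 || ss_residual < 0)
    stop("sums of squares must be non-negative")
  ms_reg <- ss_regression / df_regression
  ms_res <- ss_residual / df_residual
  ss_tot <- ss_regression + ss_residual
  Fv <- if (ms_res == 0) Inf else ms_reg / ms_res
  p <- if (ss_regression == 0) 1
       else stats::pf(Fv, df_regression, df_residual, lower.tail = FALSE)
  r2 <- if (ss_tot == 0) 0 else ss_regression / ss_tot
  n <- df_regression + df_residual + 1
  adj <- 1 - (1 - r2) * (n - 1) / df_residual
  anova <- structure(list(
    ss_regression = ss_regression, ss_residual = ss_residual,
    ss_total = ss_tot, df_regression = df_regression,
    df_residual = df_residual, df_total = df_regression + df_residual,
    ms_regression = ms_reg, ms_residual = ms_res, F = Fv, p = p),
    class = "anova_table")
  list(anova = anova,
       summary = list(r = sqrt(r2), r_square = r2, adj_r_square = adj,
                      std_error_estimate = sqrt(ms_res), p = p))
}

#' Collinearity diagnostics: tolerance and VIF
#'
#' For each predictor `j`, `tolerance_j = 1 - R2_j` where `R2_j` comes from
#' regressing predictor `j` on all the others, and `VIF_j = 1/tolerance_j`.
#' An (effectively) exact linear dependence such as a duplicated column is
#' reported as infinite VIF with zero tolerance rather than an error, so
#' the offending predictors can be inspected.
#'
#' @param X Data.frame or matrix with at least two numeric predictor
#'   columns.
#' @return Data.frame with columns `predictor`, `tolerance`, `vif`.
#' @examples
#' collinearity_stats(data.frame(a = 1:10, b = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)))
#' @export
collinearity_stats <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("need at least two predictors")
  tol <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared) # perfect fits are expected here
    max(0, 1 - r2)
  }, numeric(1))
  data.frame(predictor = names(X), tolerance = tol,
             vif = ifelse(tol < 1e-12, Inf, 1 / tol))
}

#' Durbin-Watson statistic
#'
#' `sum((e_t - e_(t-1))^2) / sum(e_t^2)` over the residual sequence; ranges
#' over \[0, 4\] with values near 2 under serial independence.
#'
#' @param residuals Numeric vector, length >= 2, not all zero.
#' @return The statistic.
#' @examples
#' durbin_watson(rep(c(1, -1), 50))  # 3.96
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2L) stop("need at least two residuals")
  if (all(residuals == 0)) stop("all-zero residuals")
  sum(diff(residuals)^2) / sum(residuals^2)
}
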