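#' L1-penalised regression of Fenton flux on RM enrichment
#'
#' Fits `fenton ~ ES` with the lasso, choosing the penalty by seeded
#' cross-validation (1-SE rule by default). Predictors are z-scored per RM
#' before fitting unless `standardize = FALSE`.
#'
#' @param fenton per-sample Fenton flux vector (the response).
#' @param es RM x sample enrichment matrix (predictors).
#' @param lambda optional fixed penalty; skips cross-validation.
#' @param lambda_grid optional penalty grid for cross-validation.
#' @param cv_folds number of CV folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param rule `"1se"` (largest penalty within one SE of the minimum) or
#'   `"min"`.
#' @param standardize z-score each RM's scores before fitting.
#' @return object of class `lasso_fit`: named `coefficients` (one per RM,
#'   on the standardised scale when `standardize = TRUE`), `intercept`,
#'   `selected` (RMs with nonzero coefficient), `lambda`, `r_squared` on the
#'   fitting data, `n` and `p`.
#' @export
lasso_fit <- function(fenton, es, lambda = NULL, lambda_grid = NULL,
                      cv_folds = 10L, seed = 1L, rule = c("1se", "min"),
                      standardize = TRUE) {
  rule <- match.arg(rule)
  y <- as.numeric(fenton)
  x <- t(es)
  n <- length(y)
  if (nrow(x) != n) stop("`fenton` and `es` sample counts differ", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("constant response: the Fenton vector has zero variance", call. = FALSE)
  }
  if (is.null(lambda) && (cv_folds < 2L || n < cv_folds)) {
    stop("need n >= cv_folds >= 2 for cross-validation", call. = FALSE)
  }
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale < 1e-12] <- 1
  if (standardize) x <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")

  if (is.null(lambda)) {
    foldid <- with_seed(seed, sample(rep(seq_len(cv_folds), length.out = n)))
    cvfit <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                               lambda = lambda_grid, standardize = FALSE)
    lambda <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, alpha = 1, standardize = FALSE)
  }
  cf <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y))
  names(cf) <- c("(Intercept)", colnames(x))
  coefficients <- cf[-1L]
  yhat <- cf[1L] + as.numeric(x %*% coefficients)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

  structure(list(coefficients = coefficients, intercept = unname(cf[1L]),
                 selected = names(coefficients)[coefficients != 0],
                 lambda = lambda, r_squared = r2, n = n, p = ncol(x),
                 standardize = standardize, center = center, scale = scale),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> n = %d, p = %d, lambda = %.4g\n", x$n, x$p, x$lambda))
  cat(sprintf("  selected %d RM(s); R^2 = %.3f\n", length(x$selected), x$r_squared))
  if (length(x$selected)) {
    sel <- sort(x$coefficients[x$selected], decreasing = TRUE)
    for (nm in names(sel)) cat(sprintf("  %s: %.4f\n", nm, sel[nm]))
  }
  invisible(x)
}

#' Predict from a lasso association fit
#'
#' @param object a [lasso_fit()].
#' @param es RM x sample enrichment matrix aligned to the fit.
#' @param ... unused.
#' @return per-sample predicted Fenton flux.
#' @export
predict.lasso_fit <- function(object, es, ...) {
  x <- t(es)[, names(object$coefficients), drop = FALSE]
  if (object$standardize) {
    x <- sweep(sweep(x, 2L, object$center, "-"), 2L, object$scale, "/")
  }
  object$intercept + as.numeric(x %*% object$coefficients)
}

#' Cross-cancer-type contribution summary
#'
#' Summarises per-type lasso fits into the averaged contribution score (mean
#' positive coefficient over the types where the RM was selected) and the
#' rate of contribution (fraction of types in which it was selected with a
#' positive coefficient).
#'
#' @param fits list of [lasso_fit()] objects, one per cancer type.
#' @param min_rate keep RMs selected in at least this fraction of types.
#' @param include_negative also count negative coefficients as selections
#'   (scores then average all nonzero coefficients).
#' @param average_over `"selected"` averages over the selecting types only;
#'   `"all"` divides the coefficient sum by the total number of types.
#' @return data.frame with `rm`, `averaged_contribution_score`,
#'   `rate_of_contribution`, sorted by score; all rates share the
#'   denominator `length(fits)`.
#' @export
contribution_summary <- function(fits, min_rate = 0.4,
                                 include_negative = FALSE,
                                 average_over = c("selected", "all")) {
  average_over <- match.arg(average_over)
  if (length(fits) == 0L) stop("need at least one fit", call. = FALSE)
  n_types <- length(fits)
  rms <- names(fits[[1L]]$coefficients)
  cf <- vapply(fits, function(f) f$coefficients[rms], numeric(length(rms)))
  cf <- matrix(cf, nrow = length(rms), dimnames = list(rms, NULL))
  hit <- if (include_negative) cf != 0 else cf > 0
  rate <- rowSums(hit) / n_types
  score <- vapply(seq_along(rms), function(i) {
    sel <- cf[i, hit[i, ]]
    if (!length(sel)) return(0)
    sum(sel) / if (average_over == "selected") length(sel) else n_types
  }, numeric(1))
  out <- data.frame(rm = rms, averaged_contribution_score = score,
                    rate_of_contribution = rate, row.names = NULL)
  out <- out[out$rate_of_contribution >= min_rate & rate > 0, , drop = FALSE]
  out[order(-out$averaged_contribution_score), , drop = FALSE]
}

#' Coefficient of determination of an association fit
#'
#' @param fit a [lasso_fit()].
#' @param fenton response vector.
#' @param es RM x sample enrichment matrix.
#' @return `1 - SSE/SST` on the provided data.
#' @export
r_squared <- function(fit, fenton, es) {
  y <- as.numeric(fenton)
  if (stats::var(y) == 0) stop("zero variance in the response", call. = FALSE)
  yhat <- predict(fit, es)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Metastasis-rate regression on sialic acid synthesis and degradation
#'
#' No-intercept two-term ordinary least squares:
#' `rate ~ 0 + sialic_synthesis + degradation_expr`, per cancer type.
#' A degradation predictor that is identically zero reduces the model to the
#' one-term regression (its coefficient is reported as 0); collinear
#' predictors trigger a warning and a pseudo-inverse solution without
#' t-tests.
#'
#' @param rates per-type metastasis rates.
#' @param sialic_synthesis per-type sialic acid synthesis levels.
#' @param degradation_expr per-type degradation-gene (e.g. NEU1) expression.
#' @return list with `coefficients` and `p_values`, both named
#'   `c("sialic_synthesis", "degradation")`.
#' @export
metastasis_regression <- function(rates, sialic_synthesis, degradation_expr) {
  n <- length(rates)
  if (n < 3L) stop("need at least 3 cancer types", call. = FALSE)
  X <- cbind(sialic_synthesis = sialic_synthesis,
             degradation = degradation_expr)
  keep <- apply(X, 2L, function(col) any(col != 0))
  coefs <- c(sialic_synthesis = 0, degradation = 0)
  pvals <- c(sialic_synthesis = NA_real_, degradation = NA_real_)
  Xk <- X[, keep, drop = FALSE]
  if (qr(Xk)$rank < ncol(Xk)) {
    warning("collinear predictors; returning the pseudo-inverse solution")
    sv <- svd(Xk)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% rates) / sv$d[pos])
    coefs[colnames(Xk)] <- as.numeric(beta)
    return(list(coefficients = coefs, p_values = pvals))
  }
  fit <- stats::lm(rates ~ 0 + Xk)
  sm <- summary(fit)$coefficients
  coefs[colnames(Xk)] <- stats::coef(fit)
  pvals[colnames(Xk)] <- sm[, "Pr(>|t|)"]
  list(coefficients = coefs, p_values = pvals)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y numeric vectors of equal length (n >= 3) with nonzero
#'   variance.
#' @return list with `estimate` (the sample correlation) and `p_value`
#'   (two-sided, t distribution with n - 2 df).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need two vectors of equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}
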