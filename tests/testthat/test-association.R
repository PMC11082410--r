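test_that("lasso recovers a planted sparse support", {
  rms <- paste0("RM", 1:40)
  coh <- generate_rm_cohort(200, rms, support = c("RM1", "RM2"),
                            beta = c(2, 1), noise_sd = 0.01, seed = 13)
  fit <- lasso_fit(coh$fenton, coh$scores, seed = 13)
  expect_true(all(c("RM1", "RM2") %in% fit$selected))
  expect_true(all(abs(fit$coefficients[setdiff(rms, c("RM1", "RM2"))]) < 0.1))

  # cross-check against the least-squares refit on the true support
  ols <- stats::lm(coh$fenton ~ t(coh$scores[c("RM1", "RM2"), ]))
  expect_equal(unname(stats::coef(ols)[-1]), c(2, 1), tolerance = 0.02)
  expect_gt(fit$r_squared, 0.95)
})

test_that("penalty limits behave as closed forms", {
  rms <- paste0("RM", 1:5)
  coh <- generate_rm_cohort(100, rms, support = c("RM1", "RM3"),
                            beta = c(1.5, -1), noise_sd = 0, seed = 2)
  # infinite penalty: everything shrinks to zero
  fit_inf <- lasso_fit(coh$fenton, coh$scores, lambda = 1e9, seed = 1)
  expect_true(all(fit_inf$coefficients == 0))

  # zero penalty, p < n, no noise: exact least-squares solution
  fit0 <- lasso_fit(coh$fenton, coh$scores, lambda = 0, seed = 1,
                    standardize = FALSE)
  ols <- stats::lm(coh$fenton ~ t(coh$scores))
  expect_equal(unname(fit0$coefficients), unname(stats::coef(ols)[-1]),
               tolerance = 1e-6)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-9)

  expect_error(lasso_fit(rep(1, 100), coh$scores), "constant")
})

test_that("the selected-set size is non-increasing along the penalty path", {
  rms <- paste0("RM", 1:15)
  coh <- generate_rm_cohort(120, rms, support = c("RM1", "RM2", "RM3"),
                            beta = c(2, 1, 0.5), noise_sd = 0.3, seed = 5)
  sizes <- vapply(c(0.001, 0.01, 0.05, 0.2, 1, 5), function(lam) {
    length(lasso_fit(coh$fenton, coh$scores, lambda = lam, seed = 1)$selected)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("contribution summary reproduces rate and score bookkeeping", {
  mk_fit <- function(coefs) {
    structure(list(coefficients = coefs,
                   selected = names(coefs)[coefs != 0]),
              class = "lasso_fit")
  }
  rms <- c("RM1", "RM2", "RM3")
  fits <- lapply(1:11, function(i) {
    co <- c(RM1 = if (i <= 9) 0.287 else 0, RM2 = 0.5, RM3 = 0)
    mk_fit(co)
  })
  cs <- contribution_summary(fits, min_rate = 0)
  expect_equal(round(cs$rate_of_contribution[cs$rm == "RM1"], 3), 0.818)
  expect_equal(cs$rate_of_contribution[cs$rm == "RM2"], 1)
  expect_false("RM3" %in% cs$rm)

  single <- contribution_summary(list(mk_fit(c(RM1 = 0.5, RM2 = 0))),
                                 min_rate = 0.4)
  expect_equal(single$averaged_contribution_score, 0.5)
  expect_equal(single$rate_of_contribution, 1)

  # every reported rate shares the same denominator
  expect_true(all(abs(cs$rate_of_contribution * 11 -
                        round(cs$rate_of_contribution * 11)) < 1e-9))
})

test_that("R-squared matches its analytic decomposition", {
  rms <- paste0("RM", 1:6)
  # signal variance 4 + 1 = 5; noise chosen for a 0.9 variance share
  sigma <- sqrt(5 / 0.9 - 5)
  coh <- generate_rm_cohort(500, rms, support = c("RM1", "RM2"),
                            beta = c(2, 1), noise_sd = sigma, seed = 21)
  fit <- lasso_fit(coh$fenton, coh$scores, lambda = 0, seed = 1)
  expect_equal(r_squared(fit, coh$fenton, coh$scores), 0.9, tolerance = 0.05)

  # intercept-only fit explains nothing
  fit0 <- lasso_fit(coh$fenton, coh$scores, lambda = 1e9, seed = 1)
  expect_equal(r_squared(fit0, coh$fenton, coh$scores), 0, tolerance = 1e-9)
  expect_error(r_squared(fit, rep(1, 500), coh$scores), "variance")
})

test_that("metastasis regression recovers the generating coefficients", {
  set.seed(3)
  x <- runif(11, 0.5, 2)
  z <- runif(11, 0, 30)
  y <- 1.91 * x - 0.039 * z
  fit <- suppressWarnings(metastasis_regression(y, x, z))
  expect_equal(unname(fit$coefficients), c(1.91, -0.039), tolerance = 1e-9)

  # permuting the type order leaves the coefficients unchanged
  perm <- sample(11)
  fit_p <- suppressWarnings(metastasis_regression(y[perm], x[perm], z[perm]))
  expect_equal(fit_p$coefficients, fit$coefficients)

  # an identically zero degradation term reduces to the one-term model
  y1 <- 1.91 * x
  fit1 <- suppressWarnings(metastasis_regression(y1, x, rep(0, 11)))
  expect_equal(unname(fit1$coefficients["sialic_synthesis"]), 1.91,
               tolerance = 1e-9)
  expect_equal(unname(fit1$coefficients["degradation"]), 0)

  expect_warning(metastasis_regression(y[1:4], x[1:4], 2 * x[1:4]), "collinear")
  expect_error(metastasis_regression(y[1:2], x[1:2], z[1:2]), "3 cancer types")
})

test_that("pearson correlation matches the closed form and the t test", {
  expect_equal(pearson_cor(1:10, 1:10)$estimate, 1)
  expect_equal(pearson_cor(1:10, 10:1)$estimate, -1)
  pc <- pearson_cor(c(1, 2, 3), c(1, 2, 4))
  expect_equal(round(pc$estimate, 4), 0.9820)

  # pearson(x, a x + b) = sign(a) exactly
  x <- rnorm(20)
  expect_equal(pearson_cor(x, 3 * x + 2)$estimate, 1)
  expect_equal(pearson_cor(x, -0.5 * x + 1)$estimate, -1)
  expect_error(pearson_cor(x, rep(1, 20)), "variance")
})
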