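test_that("total activity sums map genes or takes a constant", {
  map <- chain_map(1L)
  ex <- matrix(c(3, 4), nrow = 2, dimnames = list(c("R1G1", "R2G1"), "S1"))
  expect_equal(unname(compute_total_activity(ex, map)), 7)
  expect_equal(unname(compute_total_activity(2 * ex, map)), 14)
  expect_equal(unname(compute_total_activity(ex, map, mode = "constant", constant = 1)), 1)
  rownames(ex) <- c("X1", "X2")
  expect_error(compute_total_activity(ex, map), "no map genes")
})

test_that("imbalance and total losses evaluate the stated quadratic forms", {
  chain <- chain_map()
  f <- matrix(c(5, 5), nrow = 2, dimnames = list(c("R1", "R2"), "S1"))
  expect_equal(imbalance_loss(f, chain), 0)
  f[] <- c(2, 1)
  expect_equal(imbalance_loss(f, chain), 1)
  expect_equal(imbalance_loss(2 * f, chain), 4)  # degree-2 homogeneity

  # lambda = 0 collapses to the imbalance term exactly
  expect_identical(total_loss(f, chain, ta = c(S1 = 10), lambda = 0),
                   imbalance_loss(f, chain))
  # balanced map, total matches TA: only imbalance remains
  f[] <- c(1, 1)
  expect_equal(total_loss(f, chain, ta = 2, lambda = 1), 0)
  # no balanced metabolite: pure anchoring
  nob <- metabolic_map(c("A", "B"), balanced = character(),
                       modules = list(list(name = "R1", genes = "G1",
                                           consumes = character(), produces = "B")))
  f1 <- matrix(1, 1, 1, dimnames = list("R1", "S1"))
  expect_equal(total_loss(f1, nob, ta = 2, lambda = 1), 1)
  expect_error(total_loss(f1, nob, ta = 2, lambda = -1), "nonnegative")
})

test_that("training is deterministic given the seed and lowers the loss", {
  chain <- chain_map()
  coh <- simulate_cohort(chain, 60, seed = 10, noise_sd = 0.1)
  m1 <- fit_flux_model(coh$expression, chain, epochs = 200, seed = 5)
  m2 <- fit_flux_model(coh$expression, chain, epochs = 200, seed = 5)
  expect_identical(m1$final_loss, m2$final_loss)
  expect_identical(fitted(m1), fitted(m2))
  expect_lte(m1$final_loss, m1$initial_loss)
  expect_gte(min(fitted(m1)), 0)
})

test_that("noiseless chain cohorts train to near-zero imbalance", {
  chain <- chain_map()
  coh <- simulate_cohort(chain, 100, seed = 4, noise_sd = 0)
  m <- fit_flux_model(coh$expression, chain, lambda = 0, epochs = 1500, seed = 4)
  expect_lt(m$final_imbalance, 1e-3 * m$trace[1])
})

test_that("prediction is consistent, equivariant and nonnegative", {
  chain <- chain_map()
  coh <- simulate_cohort(chain, 40, seed = 8, noise_sd = 0.1)
  m <- fit_flux_model(coh$expression, chain, epochs = 300, seed = 8)

  # training-cohort prediction reproduces the fitted fluxes
  expect_equal(predict(m, coh$expression), fitted(m))

  # permuting samples permutes the flux columns identically
  perm <- sample(ncol(coh$expression))
  expect_equal(predict(m, coh$expression[, perm]), fitted(m)[, perm])

  # all-zero expression maps to the documented bias floor, never negative
  zero <- coh$expression * 0
  fz <- predict(m, zero)
  expect_true(all(fz >= 0))
  expect_equal(ncol(fz), ncol(zero))

  # a foreign gene namespace is an alignment error
  rownames(zero) <- paste0("ALIEN", seq_len(nrow(zero)))
  expect_error(predict(m, zero), "namespace")
})

test_that("missing module genes are zero-imputed with a warning", {
  chain <- chain_map()
  coh <- simulate_cohort(chain, 30, seed = 2, noise_sd = 0.1)
  ex <- coh$expression[-1L, ]
  expect_warning(m <- fit_flux_model(ex, chain, epochs = 50, seed = 2),
                 "absent")
  expect_s3_class(m, "flux_model")
  ex0 <- coh$expression
  rownames(ex0) <- paste0("X", seq_len(nrow(ex0)))
  expect_error(suppressWarnings(fit_flux_model(ex0, chain, epochs = 10)),
               "none of the map genes")
})

test_that("the model object supports the standard S3 surface", {
  chain <- chain_map()
  coh <- simulate_cohort(chain, 30, seed = 3, noise_sd = 0.1)
  m <- fit_flux_model(coh$expression, chain, epochs = 100, seed = 3)
  expect_output(print(m), "flux_model")
  s <- summary(m)
  expect_s3_class(s, "summary.flux_model")
  expect_named(s$flux_table, c("module", "mean_flux", "sd_flux"))
  expect_length(coef(m), 2L)
  r <- residuals(m)
  expect_equal(dim(r), c(1L, 30L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
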