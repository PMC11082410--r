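test_that("relative Fenton level is the Fenton share of the exit fluxes", {
  v <- c("Ferritin synthesis" = 1, "Heme synthesis" = 1,
         "Fe-S cluster synthesis" = 1, "Fe2+ export" = 1,
         "Fenton reaction" = 1)
  expect_equal(relative_fenton_level(v), 0.2)
  v["Fenton reaction"] <- 6
  expect_equal(relative_fenton_level(v), 0.6)
  v[] <- 0; v["Fenton reaction"] <- 3
  expect_equal(relative_fenton_level(v), 1)

  # scale invariance
  v[] <- c(2, 1, 4, 1, 2)
  expect_equal(relative_fenton_level(10 * v), relative_fenton_level(v))

  v[] <- 0
  expect_warning(out <- relative_fenton_level(v), "zero")
  expect_true(is.na(out))

  m <- rbind("Fenton reaction" = c(1, 2), "Fe2+ export" = c(3, 2))
  expect_equal(unname(relative_fenton_level(m)), c(0.25, 0.5))
})

test_that("growth rate converts doubling days to doublings per year", {
  expect_equal(growth_rate(365), 1)
  expect_equal(growth_rate(10), 36.5)
  expect_equal(round(growth_rate(103), 3), 3.544)
  expect_error(growth_rate(0), "positive")
  expect_error(growth_rate(-3), "positive")
})

test_that("bundled doubling times cover the 11 subtypes", {
  dt <- doubling_times()
  expect_equal(nrow(dt), 11L)
  expect_equal(dt$doubling_days[dt$type == "COAD"], 10)
  expect_equal(dt$doubling_days[dt$type == "BRCA_TNBC"], 103)
  expect_equal(dt$doubling_days[dt$type == "PRAD"], 900)
  expect_true(all(dt$doubling_days > 0))
})

test_that("quartile stratification is deterministic with disjoint strata", {
  v <- stats::setNames(1:8, paste0("S", 1:8))
  st <- stratify_quartiles(v, 0.25)
  expect_setequal(st$high, c("S8", "S7"))
  expect_setequal(st$low, c("S1", "S2"))

  st2 <- stratify_quartiles(stats::setNames(c(4, 2, 3, 1), paste0("S", 1:4)), 0.5)
  expect_length(st2$high, 2L)
  expect_length(st2$low, 2L)
  expect_length(intersect(st2$high, st2$low), 0L)

  expect_warning(tie <- stratify_quartiles(stats::setNames(rep(1, 8),
                                                           paste0("S", 1:8))),
                 "equal")
  expect_equal(tie$high, c("S1", "S2"))
  expect_setequal(tie$low, c("S7", "S8"))
  expect_length(intersect(tie$high, tie$low), 0L)

  expect_error(stratify_quartiles(stats::setNames(1:2, c("a", "b")), 0.25),
               "too few")

  # property over random draws: disjoint and of size floor(q n)
  set.seed(1)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    q <- runif(1, 0.1, 0.5)
    vv <- stats::setNames(rnorm(n), paste0("S", seq_len(n)))
    st <- stratify_quartiles(vv, q)
    expect_length(st$high, floor(q * n))
    expect_length(st$low, floor(q * n))
    expect_length(intersect(st$high, st$low), 0L)
  }
})

test_that("Mann-Whitney U and exact enumeration match first principles", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 2 / 6)
  expect_equal(mw$method, "exact")

  # identical samples: U = nm/2 by symmetry
  a <- c(1, 5, 9)
  mw2 <- mann_whitney(a, a)
  expect_equal(mw2$statistic, length(a)^2 / 2)

  # U_a + U_b = nm always, including ties
  set.seed(2)
  for (i in 1:20) {
    x <- sample(1:6, sample(2:9, 1), replace = TRUE)
    y <- sample(1:6, sample(2:9, 1), replace = TRUE)
    ua <- mann_whitney(x, y)$statistic
    ub <- mann_whitney(y, x)$statistic
    expect_equal(ua + ub, length(x) * length(y))
  }
})

test_that("exact and normal-approximation P values agree closely at n = 8 + 8", {
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(8)
    b <- rnorm(8, mean = runif(1, -1, 1))
    pe <- mann_whitney(a, b, method = "exact")$p_value
    pn <- mann_whitney(a, b, method = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("exact P matches stats::wilcox.test on tie-free data", {
  set.seed(9)
  a <- rnorm(6); b <- rnorm(7)
  expect_equal(mann_whitney(a, b, method = "exact")$p_value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("phenotype correlation reuses the Pearson t test", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5)
  expect_equal(correlate_phenotype(x, x)$estimate, 1)
  expect_error(correlate_phenotype(x, rep(2, 11)), "variance")

  # a PCC of 0.635 at n = 11 is significant at the 5% level by the t formula
  r <- 0.635; n <- 11
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  expect_lt(p, 0.05)
  expect_equal(round(p, 3), 0.036)
})
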