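# independent brute-force oracle: literal running sum over the ranked list
oracle_es <- function(expr, gene_set, alpha) {
  ord <- order(-expr, names(expr), method = "radix")
  expr <- expr[ord]
  hit <- names(expr) %in% gene_set
  G <- length(expr)
  es <- 0
  for (i in seq_len(G)) {
    w <- abs(expr[seq_len(i)])^alpha
    p_hit <- sum(w[hit[seq_len(i)]]) / sum(abs(expr)[hit]^alpha)
    p_miss <- if (G > sum(hit)) sum(!hit[seq_len(i)]) / (G - sum(hit)) else 0
    es <- es + p_hit - p_miss
  }
  unname(es)
}

test_that("the running-sum score matches the hand-enumerated example", {
  expr <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
  # set = top gene, alpha = 0: P_hit = 1 at every rank, P_miss = (i-1)/4
  expect_equal(ssgsea_score(expr, "g1", alpha = 0), 2.5)
  expect_equal(oracle_es(expr, "g1", 0), 2.5)
})

test_that("scores agree with the brute-force oracle on all small universes", {
  genes <- paste0("g", 1:5)
  set.seed(42)
  for (rep in 1:20) {
    expr <- stats::setNames(round(stats::runif(5, 0.1, 10), 2), genes)
    for (k in 1:2) {
      for (set_idx in utils::combn(5, k, simplify = FALSE)) {
        for (alpha in c(0, 0.75, 1)) {
          expect_equal(ssgsea_score(expr, genes[set_idx], alpha),
                       oracle_es(expr, genes[set_idx], alpha),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("top-ranked sets outscore bottom-ranked sets for any alpha", {
  expr <- stats::setNames(seq(10, 1), paste0("g", 1:10))
  for (alpha in c(0, 0.5, 0.75, 1, 2)) {
    expect_gt(ssgsea_score(expr, paste0("g", 1:5), alpha),
              ssgsea_score(expr, paste0("g", 6:10), alpha))
  }
})

test_that("alpha = 0 scores are rank-only and ties break deterministically", {
  set.seed(7)
  expr <- stats::setNames(stats::rexp(20), paste0("g", 1:20))
  set <- c("g3", "g11", "g17")
  monotone <- function(x) log1p(x) * 3 + 1
  expect_equal(ssgsea_score(expr, set, alpha = 0),
               ssgsea_score(monotone(expr), set, alpha = 0))

  tied <- stats::setNames(rep(1, 5), c("b", "a", "d", "c", "e"))
  es <- ssgsea_score(tied, c("a", "b"), alpha = 0)
  # lexicographic tie-break puts a, b first: same as a strict ordering oracle
  strict <- stats::setNames(c(5, 4, 3, 2, 1), c("a", "b", "c", "d", "e"))
  expect_equal(es, ssgsea_score(strict, c("a", "b"), alpha = 0))
})

test_that("all-zero set weights fall back to rank weighting", {
  # a set gene stuck at zero expression has zero weight for alpha > 0;
  # the documented policy reverts to unit (rank) weights
  expr <- c(g1 = 4, g2 = 0, g3 = 2, g4 = 1, g5 = 3)
  expect_equal(ssgsea_score(expr, "g2", alpha = 0.75),
               ssgsea_score(expr, "g2", alpha = 0))
})

test_that("missing set genes yield NA with a warning", {
  expr <- c(g1 = 1, g2 = 2)
  expect_warning(es <- ssgsea_score(expr, "absent"), "no gene")
  expect_true(is.na(es))
})

test_that("the bundled collection matches the curated table", {
  sets <- default_rm_sets()
  expect_length(sets, 43L)
  expect_equal(sets[["Keratan sulfate synthesis"]], "CHST1")
  expect_setequal(sets[["Triglyceride degradation"]],
                  c("LIPE", "PNLIP", "DAGLB", "DAGLA"))
  expect_setequal(sets[["Sialic acid synthesis"]],
                  c("GNE", "NANS", "NANP", "CMAS", "SLC35A1"))
  expect_true(all(lengths(sets) >= 1L))
})

test_that("GMT files round-trip and duplicates are rejected", {
  sets <- list(SetA = c("G1", "G2"), SetB = "G3")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  writeLines(c("S\tdesc\tG1", "S\tdesc\tG2"), path)
  expect_error(read_gmt(path), "duplicate")
})

test_that("the score matrix composes per-sample scores", {
  set.seed(1)
  ex <- matrix(stats::rexp(40), nrow = 10,
               dimnames = list(paste0("g", 1:10), paste0("S", 1:4)))
  sets <- list(A = c("g1", "g2", "g3"), B = c("g8", "g9"))
  es <- ssgsea_matrix(ex, sets, alpha = 0.75)
  expect_equal(dim(es), c(2L, 4L))
  v <- ex[, 2]; names(v) <- rownames(ex)
  expect_equal(es["A", 2], ssgsea_score(v, sets$A, 0.75))

  # permuting samples permutes columns; duplicated sample duplicates scores
  expect_equal(ssgsea_matrix(ex[, c(3, 1, 4, 2)], sets, 0.75), es[, c(3, 1, 4, 2)])
  exd <- cbind(ex, ex[, 4, drop = FALSE])
  esd <- ssgsea_matrix(exd, sets, 0.75)
  expect_equal(esd[, 5], esd[, 4], ignore_attr = TRUE)
})
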