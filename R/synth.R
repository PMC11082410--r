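#' Generate ground-truth fluxes satisfying flux balance
#'
#' Draws a nonnegative module-by-sample flux matrix in which, for every
#' balanced metabolite and every sample, total influx matches total outflux
#' to within the requested slack. Source modules (those consuming no
#' balanced metabolite) are drawn log-normally; the influx of each balanced
#' pool is then apportioned to its consumers by Dirichlet shares, and a
#' final alternating projection (onto the balance subspace and the
#' nonnegative orthant) cleans residual imbalance on maps where one module
#' couples several pools.
#'
#' @param map a [metabolic_map()].
#' @param n_samples number of samples (columns).
#' @param seed integer seed; the draw is bit-reproducible given
#'   `(seed, parameters)`.
#' @param slack nonnegative relative tolerance: per balanced metabolite and
#'   sample, `|influx - outflux| <= slack * influx` (machine-level residuals
#'   are accepted when `slack = 0`).
#' @param meanlog,sdlog log-normal parameters for source-module fluxes.
#' @param dirichlet_conc concentration of the per-sample Dirichlet shares
#'   apportioning influx to consumers.
#' @return nonnegative matrix, modules x samples.
#' @export
generate_fluxes <- function(map, n_samples, seed = 1L, slack = 0.01,
                            meanlog = 0, sdlog = 0.5, dirichlet_conc = 5) {
  stopifnot(inherits(map, "metabolic_map"))
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(slack, "slack", lower = 0)
  # a metabolite with producers but no consumers in the balanced set cannot
  # be balanced at nonzero flux
  for (ck in map$balanced) {
    ff <- fin_fout(map, ck)
    if (length(ff$consumers) == 0L) {
      stop(sprintf("infeasible map: balanced metabolite '%s' has producers but no consumers",
                   ck), call. = FALSE)
    }
  }
  mods <- module_names(map)
  M <- length(mods)
  n <- as.integer(n_samples)
  consumed_balanced <- lapply(map$modules, function(m) intersect(m$consumes, map$balanced))
  names(consumed_balanced) <- mods
  sources <- mods[vapply(consumed_balanced, length, integer(1)) == 0L]

  with_seed(seed, {
    flux <- matrix(NA_real_, nrow = M, ncol = n,
                   dimnames = list(mods, paste0("S", seq_len(n))))
    flux[sources, ] <- matrix(
      stats::rlnorm(length(sources) * n, meanlog, sdlog),
      nrow = length(sources))

    # topological apportioning over balanced pools
    done_mets <- character()
    repeat {
      ready <- Filter(function(ck) {
        ff <- fin_fout(map, ck)
        !(ck %in% done_mets) && !anyNA(flux[ff$producers, , drop = FALSE])
      }, map$balanced)
      if (length(ready) == 0L) break
      for (ck in ready) {
        ff <- fin_fout(map, ck)
        influx <- colSums(flux[ff$producers, , drop = FALSE])
        fixed <- ff$consumers[!is.na(flux[ff$consumers, 1L])]
        free <- setdiff(ff$consumers, fixed)
        if (length(free) == 0L) { done_mets <- c(done_mets, ck); next }
        # per-sample Dirichlet shares over the free consumers of the influx
        # remaining after already-assigned (multi-pool) consumers
        g <- matrix(stats::rgamma(length(free) * n, shape = dirichlet_conc),
                    nrow = length(free))
        shares <- sweep(g, 2L, colSums(g), "/")
        remaining <- influx - if (length(fixed)) colSums(flux[fixed, , drop = FALSE]) else 0
        remaining <- pmax(remaining, 1e-8)
        flux[free, ] <- shares * rep(remaining, each = length(free))
        done_mets <- c(done_mets, ck)
      }
    }
    if (anyNA(flux)) {
      # modules consuming only pools that never became ready (cyclic maps):
      # seed them log-normally and leave the polish to the projection
      flux[is.na(flux)] <- stats::rlnorm(sum(is.na(flux)), meanlog, sdlog)
    }

    flux <- .project_balance(flux, map, slack)
    flux
  })
}

# Alternating projection onto {S_b f = 0} and {f >= 0}; stops once each
# balanced metabolite's per-sample residual is within the slack.
.project_balance <- function(flux, map, slack, max_iter = 2000L) {
  Sb <- stoich_matrix(map, balanced_only = TRUE)
  if (nrow(Sb) == 0L) return(flux)
  SSt_inv <- solve(Sb %*% t(Sb))
  P <- t(Sb) %*% SSt_inv
  ok <- function(f) {
    r <- Sb %*% f
    influx <- pmax(Sb, 0) %*% f
    tol <- pmax(slack * influx, 1e-8)
    all(abs(r) <= tol) && min(f) >= -1e-10
  }
  for (i in seq_len(max_iter)) {
    if (ok(flux)) break
    flux <- flux - P %*% (Sb %*% flux)   # affine projection
    if (ok(flux)) break
    flux <- pmax(flux, 0)                # nonnegativity
  }
  flux <- pmax(flux, 0)
  if (!ok(flux)) {
    stop("flux generation did not reach the requested balance slack; ",
         "the map may admit no positive balanced flux", call. = FALSE)
  }
  flux
}

#' Generate module-linked expression from ground-truth fluxes
#'
#' Each module's member genes are a positive per-gene loading times a
#' monotone link of the module flux, under multiplicative log-normal noise:
#' `expr = loading * link(flux) * exp(N(0, noise_sd))`. Gene names come from
#' the map membership and are padded with synthetic symbols when
#' `genes_per_module` exceeds the membership size.
#'
#' @param true_flux modules x samples matrix, e.g. from [generate_fluxes()].
#' @param map the [metabolic_map()] the fluxes refer to.
#' @param genes_per_module genes simulated per module; `NULL` uses each
#'   module's full membership.
#' @param link `"linear"` (identity) or `"log"` (`log1p`).
#' @param noise_sd standard deviation of the log-scale noise.
#' @param seed integer seed.
#' @param loading_range range of the Uniform per-gene loadings; `c(1, 1)`
#'   fixes all loadings to 1.
#' @return nonnegative genes x samples matrix (TPM-scale up to the flux scale).
#' @export
generate_expression <- function(true_flux, map, genes_per_module = NULL,
                                link = c("linear", "log"), noise_sd = 0.2,
                                seed = 1L, loading_range = c(0.5, 2)) {
  stopifnot(inherits(map, "metabolic_map"))
  link <- match.arg(link)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(genes_per_module)) {
    assert_scalar_number(genes_per_module, "genes_per_module", lower = 1)
  }
  linkf <- switch(link, linear = identity, log = log1p)
  n <- ncol(true_flux)
  rows <- list()
  with_seed(seed, {
    for (m in map$modules) {
      genes <- m$genes
      if (!is.null(genes_per_module)) {
        k <- as.integer(genes_per_module)
        if (k <= length(genes)) {
          genes <- genes[seq_len(k)]
        } else {
          pad <- paste0(gsub("[^A-Za-z0-9]+", "_", toupper(m$name)), "_SYN",
                        seq_len(k - length(genes)))
          genes <- c(genes, pad)
        }
      }
      f <- linkf(true_flux[m$name, ])
      loading <- stats::runif(length(genes), loading_range[1], loading_range[2])
      noise <- matrix(exp(stats::rnorm(length(genes) * n, 0, noise_sd)),
                      nrow = length(genes))
      block <- loading * matrix(rep(f, each = length(genes)), nrow = length(genes)) * noise
      rownames(block) <- genes
      rows[[m$name]] <- block
    }
  })
  expr <- do.call(rbind, rows)
  colnames(expr) <- colnames(true_flux)
  if (anyDuplicated(rownames(expr))) {
    warning("genes shared between modules were summed across their modules")
    expr <- rowsum(expr, group = rownames(expr))
  }
  expr
}

#' Generate an RM-enrichment cohort linearly coupled to a Fenton flux
#'
#' Standard-normal RM scores plus a Fenton-flux vector that is a linear
#' combination of a supported subset of RMs with Gaussian noise:
#' `fenton = sum(beta_r * score_r) + N(0, noise_sd)`.
#'
#' @param n_samples number of samples.
#' @param rm_names character vector of RM names (rows of the score matrix).
#' @param support subset of `rm_names` with nonzero effect.
#' @param beta effect sizes, one per supported RM.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return list with `scores` (RM x sample matrix) and `fenton`
#'   (length-`n_samples` vector).
#' @export
generate_rm_cohort <- function(n_samples, rm_names, support = character(),
                               beta = numeric(), noise_sd = 0.1, seed = 1L) {
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (!all(support %in% rm_names)) {
    stop("`support` must be a subset of `rm_names`", call. = FALSE)
  }
  if (length(beta) != length(support)) {
    stop("`beta` must have one effect size per supported RM", call. = FALSE)
  }
  n <- as.integer(n_samples)
  with_seed(seed, {
    scores <- matrix(stats::rnorm(length(rm_names) * n), nrow = length(rm_names),
                     dimnames = list(rm_names, paste0("S", seq_len(n))))
    fenton <- if (length(support)) {
      as.numeric(crossprod(scores[support, , drop = FALSE], beta))
    } else {
      rep(0, n)
    }
    fenton <- fenton + stats::rnorm(n, 0, noise_sd)
    names(fenton) <- colnames(scores)
    list(scores = scores, fenton = fenton)
  })
}

#' Shuffle expression of selected genes within a random sample subset
#'
#' In `floor(fraction * N)` randomly chosen samples, each listed gene's
#' values are permuted among those samples (per-gene, independent
#' permutations restricted to the chosen subset). Entries outside the subset
#' are untouched; per-gene value multisets are preserved.
#'
#' @param expression genes x samples matrix.
#' @param fraction fraction of samples to perturb, in \[0, 1\].
#' @param seed integer seed.
#' @param genes genes to perturb; defaults to all rows.
#' @return a matrix of the same shape.
#' @export
shuffle_perturbation <- function(expression, fraction, seed = 1L,
                                 genes = rownames(expression)) {
  assert_scalar_number(fraction, "fraction", lower = 0, upper = 1)
  n <- ncol(expression)
  k <- floor(fraction * n)
  if (k < 2L) return(expression)
  genes <- intersect(genes, rownames(expression))
  with_seed(seed, {
    chosen <- sample.int(n, k)
    for (g in genes) {
      expression[g, chosen] <- expression[g, chosen][sample.int(k)]
    }
    expression
  })
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: balanced ground-truth fluxes via [generate_fluxes()]
#' and module-linked expression via [generate_expression()], with sub-seeds
#' derived from one cohort seed.
#'
#' @inheritParams generate_fluxes
#' @inheritParams generate_expression
#' @return list with `expression`, `true_flux`, `map` and `seed`.
#' @export
simulate_cohort <- function(map, n_samples, seed = 1L, noise_sd = 0.2,
                            slack = 0.01, link = "linear",
                            genes_per_module = NULL,
                            loading_range = c(0.5, 2)) {
  seed <- as.integer(seed)
  true_flux <- generate_fluxes(map, n_samples, seed = seed, slack = slack)
  expression <- generate_expression(true_flux, map,
                                    genes_per_module = genes_per_module,
                                    link = link, noise_sd = noise_sd,
                                    seed = seed + 1L,
                                    loading_range = loading_range)
  list(expression = expression, true_flux = true_flux, map = map, seed = seed)
}
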