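#' Relative Fenton reaction level
#'
#' The Fenton share of the summed flux of the cytosolic iron exit modules:
#' `Fenton / sum(exit fluxes)`, in \[0, 1\] and invariant to rescaling all
#' fluxes by a positive constant.
#'
#' @param fluxes named nonnegative vector of the iron-exit fluxes (Fenton
#'   among them), or a modules x samples matrix whose rows are the exit
#'   modules.
#' @param fenton name of the Fenton module.
#' @return a fraction (or one per sample for matrix input); `NA` with a
#'   warning when all exit fluxes are zero.
#' @export
relative_fenton_level <- function(fluxes, fenton = "Fenton reaction") {
  if (is.matrix(fluxes)) {
    if (!fenton %in% rownames(fluxes)) {
      stop("Fenton module '", fenton, "' not among the flux rows", call. = FALSE)
    }
    tot <- colSums(fluxes)
    out <- fluxes[fenton, ] / tot
    if (any(tot == 0)) {
      warning("all exit fluxes zero in some sample(s); returning NA there")
      out[tot == 0] <- NA_real_
    }
    return(out)
  }
  if (is.null(names(fluxes)) || !fenton %in% names(fluxes)) {
    stop("Fenton module '", fenton, "' not among the flux names", call. = FALSE)
  }
  if (any(fluxes < 0)) stop("fluxes must be nonnegative", call. = FALSE)
  tot <- sum(fluxes)
  if (tot == 0) {
    warning("all exit fluxes are zero; relative level undefined")
    return(NA_real_)
  }
  unname(fluxes[fenton] / tot)
}

#' Tumour growth rate from doubling time
#'
#' @param doubling_days median tumour volume doubling time in days (> 0).
#' @return doublings per year, `365 / doubling_days`.
#' @export
growth_rate <- function(doubling_days) {
  if (any(!is.finite(doubling_days)) || any(doubling_days <= 0)) {
    stop("doubling time must be positive", call. = FALSE)
  }
  365 / doubling_days
}

#' Bundled median tumour doubling times per cancer subtype
#'
#' @return data.frame with `type` and `doubling_days` for the 11 cancer
#'   subtypes.
#' @export
doubling_times <- function() {
  utils::read.delim(system.file("extdata", "doubling_times.tsv",
                                package = "fentonflux", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Read a phenotype table
#'
#' TSV with columns `type`, `doubling_days` and optionally
#' `metastasis_rate`.
#'
#' @param path path to the table.
#' @return validated data.frame.
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("type", "doubling_days") %in% names(tab))) {
    stop("phenotype table needs columns 'type' and 'doubling_days'", call. = FALSE)
  }
  if (any(tab$doubling_days <= 0)) {
    stop("doubling times must be positive", call. = FALSE)
  }
  tab
}

#' Stratify samples into top and bottom value fractions
#'
#' Returns the `floor(q * n)` samples with the highest and with the lowest
#' values; ties are broken by sample label so the split is deterministic.
#'
#' @param values named per-sample vector (names default to indices).
#' @param q fraction in (0, 0.5\] per stratum.
#' @return list with character vectors `high` and `low`, disjoint and each
#'   of size `floor(q * n)`.
#' @export
stratify_quartiles <- function(values, q = 0.25) {
  assert_scalar_number(q, "q", lower = 1e-12, upper = 0.5)
  n <- length(values)
  k <- floor(q * n)
  if (k < 1L) stop("too few samples: floor(q * n) < 1", call. = FALSE)
  if (is.null(names(values))) names(values) <- as.character(seq_len(n))
  if (length(unique(values)) == 1L) {
    warning("all values equal; stratifying by sample label order")
  }
  # one deterministic ordering; strata from opposite ends stay disjoint
  # even when values tie across the boundary
  ord <- order(-values, names(values), method = "radix")
  list(high = names(values)[ord[seq_len(k)]],
       low = names(values)[rev(ord)[seq_len(k)]])
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with midrank ties. The two-sided P value comes from full
#' enumeration of the rank assignments when the pooled size is at most 16
#' (valid under ties), and otherwise from the normal approximation with tie
#' and continuity corrections.
#'
#' @param a,b numeric samples.
#' @param method `"auto"` (enumeration up to pooled size 16), `"exact"` or
#'   `"normal"`.
#' @return list with `statistic` (U of sample `a`), `p_value` and the
#'   `method` used. `U_a + U_b = length(a) * length(b)` always.
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (method == "auto") method <- if (na + nb <= 16L) "exact" else "normal"
  if (method == "exact") {
    sets <- utils::combn(na + nb, na)
    usum <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    p_lo <- mean(usum <= u + 1e-9)
    p_hi <- mean(usum >= u - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
  list(statistic = u, p_value = p, method = method)
}

#' Correlate a per-type statistic with a phenotype
#'
#' Thin wrapper over [pearson_cor()] for flux-derived cohort statistics
#' against phenotype vectors such as growth rates.
#'
#' @param per_type_stat per-cancer-type statistic.
#' @param phenotype matching phenotype vector.
#' @return list with `estimate` and `p_value`.
#' @export
correlate_phenotype <- function(per_type_stat, phenotype) {
  pearson_cor(per_type_stat, phenotype)
}
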