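#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member gene symbols.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name(s) in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) {
    genes <- f[-c(1L, 2L)]
    genes[nzchar(genes)]
  })
  names(sets) <- nms
  empty <- nms[vapply(sets, length, integer(1)) == 0L]
  if (length(empty)) {
    stop("gene set(s) with no genes: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "gene set") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The bundled collection of 43 reprogrammed-metabolism gene sets
#'
#' Acid-producing reprogrammed metabolisms (RMs) — amino-acid, nucleotide,
#' lipid, glycan and related pathways — each defined by its marker genes.
#'
#' @return named list of 43 character vectors.
#' @export
default_rm_sets <- function() {
  read_gmt(system.file("extdata", "rm_gene_sets.gmt",
                       package = "fentonflux", mustWork = TRUE))
}

#' Single-sample gene-set enrichment score
#'
#' The ssGSEA running-sum statistic: genes are ranked by descending
#' expression (ties broken by gene symbol, deterministically); at each rank
#' the cumulative `|expr|^alpha`-weighted fraction of set genes is compared
#' with the cumulative fraction of non-set genes, and the enrichment score
#' is the sum of the differences over all ranks (the running-sum integral,
#' not the Kolmogorov-Smirnov extremum).
#'
#' @param expr named numeric vector: one sample's expression.
#' @param gene_set character vector of set genes.
#' @param alpha nonnegative rank-weight exponent; `alpha = 0` makes the
#'   score depend on ranks only.
#' @return the enrichment score, or `NA` (with a warning) when no set gene
#'   is present in the vector.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.75) {
  assert_scalar_number(alpha, "alpha", lower = 0)
  if (is.null(names(expr))) stop("`expr` must be a named vector", call. = FALSE)
  in_set <- names(expr) %in% gene_set
  if (!any(in_set)) {
    warning("no gene of the set is present in the expression vector")
    return(NA_real_)
  }
  ord <- order(-expr, names(expr), method = "radix")
  expr <- expr[ord]
  in_set <- in_set[ord]
  G <- length(expr)
  n_set <- sum(in_set)
  w <- abs(expr)^alpha * in_set
  if (sum(w) <= 0) w <- as.numeric(in_set)  # all-zero weights: fall back to ranks
  p_hit <- cumsum(w) / sum(w)
  p_miss <- if (G > n_set) cumsum(!in_set) / (G - n_set) else rep(0, G)
  sum(p_hit - p_miss)
}

#' Enrichment scores for a collection over a cohort
#'
#' @param expression genes x samples matrix.
#' @param collection named list of gene sets, e.g. [default_rm_sets()].
#' @param alpha rank-weight exponent, see [ssgsea_score()].
#' @param normalize divide all scores by the overall (max - min) range for
#'   cross-cohort comparability.
#' @return sets x samples matrix of enrichment scores.
#' @export
ssgsea_matrix <- function(expression, collection, alpha = 0.75,
                          normalize = FALSE) {
  es <- matrix(NA_real_, nrow = length(collection), ncol = ncol(expression),
               dimnames = list(names(collection), colnames(expression)))
  for (j in seq_len(ncol(expression))) {
    v <- expression[, j]
    names(v) <- rownames(expression)
    for (s in names(collection)) {
      es[s, j] <- ssgsea_score(v, collection[[s]], alpha = alpha)
    }
  }
  if (normalize) {
    rng <- range(es, na.rm = TRUE)
    if (diff(rng) > 0) es <- es / diff(rng)
  }
  es
}
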