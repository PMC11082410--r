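#' Read a gene-by-sample expression matrix
#'
#' TSV (or CSV, by extension) with a header row of sample IDs and gene
#' symbols in the first column. Duplicate gene rows are collapsed by summing
#' with a warning; non-numeric cells are parse errors naming the position.
#'
#' @param path path to the table.
#' @return numeric genes x samples matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "character", quote = "\""),
    error = function(e) stop("cannot parse expression file: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop("expression file has no data rows or no sample columns", call. = FALSE)
  }
  genes <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num) && !anyNA(vals)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                 vals[bad[1L], bad[2L]], bad[1L], colnames(vals)[bad[2L]]),
         call. = FALSE)
  }
  rownames(num) <- genes
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning("duplicate gene symbols collapsed by sum: ",
            paste(utils::head(dups, 5L), collapse = ", "))
    num <- rowsum(num, group = genes)
  }
  num
}

#' Write an expression (or flux) matrix to TSV/CSV
#'
#' Inverse of [read_expression()]; round-trips bit-identically for
#' duplicate-free matrices.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path (`.csv` switches to comma separation).
#' @param id_column header of the first (row-name) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_column = "gene") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' Per sample `j`: `TPM_gj = FPKM_gj / sum_g FPKM_gj * 1e6`, so every column
#' sums to one million. Idempotent up to scale.
#'
#' @param mat nonnegative genes x samples FPKM matrix.
#' @return TPM matrix of the same shape.
#' @export
fpkm_to_tpm <- function(mat) {
  if (any(mat < 0)) stop("FPKM values must be nonnegative", call. = FALSE)
  cs <- colSums(mat)
  if (any(cs == 0)) {
    stop("all-zero sample column(s): ",
         paste(utils::head(colnames(mat)[cs == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  sweep(mat, 2L, cs, "/") * 1e6
}

.pipeline_defaults <- function() {
  list(expression = NULL, map = NULL, gene_sets = NULL,
       lambda = 1, epochs = 1000L, seed = 1L, alpha = 0.75, q = 0.25,
       out_dir = NULL, normalize_es = FALSE, pooled_fit = TRUE,
       bh_correction = FALSE)
}

#' Run the full transcriptome-to-report pipeline
#'
#' Reads (or accepts) an expression matrix, fits the flux model on the map,
#' scores the RM gene sets, regresses the Fenton flux on the enrichment
#' scores, stratifies samples by Fenton level, and writes `flux.tsv`,
#' `es.tsv`, `association_summary.tsv`, `phenotype_report.tsv` and
#' `manifest.json` to the output directory. All randomness flows from the
#' single `seed`; re-running with the same configuration reproduces the
#' outputs bit-identically.
#'
#' @param config named list (or path to a JSON file) with fields
#'   `expression` (path or matrix, required), `out_dir` (required), and
#'   optionally `map` (path; bundled iron map by default), `gene_sets`
#'   (GMT path; bundled RM collection by default), `lambda`, `epochs`,
#'   `seed`, `alpha`, `q`, `normalize_es`, `pooled_fit`, `bh_correction`.
#'   Unknown fields are a validation error.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$expression)) stop("config needs `expression`", call. = FALSE)
  if (is.null(cfg$out_dir)) stop("config needs `out_dir`", call. = FALSE)

  map <- if (is.null(cfg$map)) {
    default_iron_map()
  } else if (inherits(cfg$map, "metabolic_map")) cfg$map else read_metabolic_map(cfg$map)
  sets <- if (is.null(cfg$gene_sets)) {
    default_rm_sets()
  } else if (is.list(cfg$gene_sets)) cfg$gene_sets else read_gmt(cfg$gene_sets)
  expr <- if (is.matrix(cfg$expression)) cfg$expression else read_expression(cfg$expression)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  message("[pipeline] flux estimation")
  model <- fit_flux_model(expr, map, lambda = cfg$lambda, epochs = cfg$epochs,
                          seed = cfg$seed)
  flux <- fitted(model)
  write_expression(flux, file.path(cfg$out_dir, "flux.tsv"), id_column = "module")

  message("[pipeline] RM enrichment scoring")
  covered <- mean(unlist(sets) %in% rownames(expr))
  message(sprintf("[pipeline] %.0f%% of RM genes present in the matrix", 100 * covered))
  es <- ssgsea_matrix(expr, sets, alpha = cfg$alpha, normalize = cfg$normalize_es)
  write_expression(es, file.path(cfg$out_dir, "es.tsv"), id_column = "rm")

  message("[pipeline] association analysis")
  fenton_name <- if ("Fenton reaction" %in% rownames(flux)) "Fenton reaction" else rownames(flux)[1L]
  keep <- !apply(es, 1L, function(r) anyNA(r) || stats::sd(r) == 0)
  if (sum(keep) >= 2L) {
    fit <- lasso_fit(flux[fenton_name, ], es[keep, , drop = FALSE], seed = cfg$seed)
    assoc <- data.frame(rm = names(fit$coefficients),
                        coefficient = unname(fit$coefficients),
                        selected = names(fit$coefficients) %in% fit$selected)
    assoc_r2 <- fit$r_squared
  } else {
    message("[pipeline] fewer than 2 scorable RM sets; association skipped")
    assoc <- data.frame(rm = character(), coefficient = numeric(),
                        selected = logical())
    assoc_r2 <- NA
  }
  utils::write.table(assoc, file.path(cfg$out_dir, "association_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("[pipeline] phenotype report")
  exits <- intersect(iron_exit_modules(map), rownames(flux))
  rel <- relative_fenton_level(flux[exits, , drop = FALSE], fenton = fenton_name)
  strata <- stratify_quartiles(stats::setNames(flux[fenton_name, ], colnames(flux)),
                               q = cfg$q)
  report <- data.frame(
    sample = colnames(flux),
    fenton_flux = unname(flux[fenton_name, ]),
    relative_fenton_level = unname(rel),
    stratum = ifelse(colnames(flux) %in% strata$high, "high",
                     ifelse(colnames(flux) %in% strata$low, "low", "mid")))
  utils::write.table(report, file.path(cfg$out_dir, "phenotype_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "fentonflux",
    version = as.character(utils::packageVersion("fentonflux")),
    seed = cfg$seed,
    config = cfg[c("lambda", "epochs", "seed", "alpha", "q",
                   "normalize_es", "pooled_fit", "bh_correction")],
    n_samples = ncol(expr), n_genes = nrow(expr),
    epochs_run = model$epochs_run,
    final_loss = model$final_loss,
    final_imbalance = model$final_imbalance,
    association_r_squared = assoc_r2)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}
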