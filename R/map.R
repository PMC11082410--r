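#' Construct a factor-graph metabolic map
#'
#' A metabolic map is a bipartite factor graph of metabolite pools and
#' reaction modules. Each module carries the genes whose expression drives
#' its flux, the metabolites it consumes and the metabolites it produces.
#' Flux balance is imposed only on the `balanced` subset of metabolites:
#' intermediate pools with both producers and consumers. Terminal products
#' (e.g. the hydroxyl radical released by the Fenton reaction) are
#' represented but not penalised.
#'
#' @param metabolites character vector of metabolite pool identifiers.
#' @param modules list of modules; each a list with fields `name` (character),
#'   `genes` (non-empty character vector), `consumes` and `produces`
#'   (possibly empty character vectors of metabolite identifiers) and an
#'   optional free-text `note`.
#' @param balanced character vector, subset of `metabolites`, on which the
#'   flux-imbalance penalty applies. Every balanced metabolite must have at
#'   least one producing and one consuming module.
#' @param name,description optional free-text metadata.
#'
#' @return An object of class `metabolic_map`.
#' @seealso [read_metabolic_map()], [default_iron_map()], [fin_fout()],
#'   [stoich_matrix()]
#' @export
metabolic_map <- function(metabolites, modules, balanced = character(),
                          name = NULL, description = NULL) {
  metabolites <- as.character(metabolites)
  if (anyDuplicated(metabolites)) {
    stop("duplicate metabolite identifiers: ",
         paste(unique(metabolites[duplicated(metabolites)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(modules) == 0L) stop("map must contain at least one module", call. = FALSE)
  modules <- lapply(modules, function(m) {
    list(name = as.character(m$name %||% stop("module without a name", call. = FALSE)),
         genes = as.character(m$genes %||% character()),
         consumes = as.character(m$consumes %||% character()),
         produces = as.character(m$produces %||% character()),
         note = as.character(m$note %||% ""))
  })
  mod_names <- vapply(modules, `[[`, character(1), "name")
  if (anyDuplicated(mod_names)) {
    stop("duplicate module names: ",
         paste(unique(mod_names[duplicated(mod_names)]), collapse = ", "),
         call. = FALSE)
  }
  for (m in modules) {
    if (length(m$genes) == 0L) {
      stop(sprintf("module '%s' has no genes", m$name), call. = FALSE)
    }
    bad <- setdiff(c(m$consumes, m$produces), metabolites)
    if (length(bad)) {
      stop(sprintf("module '%s' references undeclared metabolite(s): %s",
                   m$name, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  balanced <- as.character(balanced)
  bad <- setdiff(balanced, metabolites)
  if (length(bad)) {
    stop("balanced set references undeclared metabolite(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  map <- structure(
    list(metabolites = metabolites, modules = modules, balanced = balanced,
         name = name %||% "metabolic map", description = description %||% ""),
    class = "metabolic_map")
  for (ck in balanced) {
    ff <- fin_fout(map, ck)
    if (length(ff$producers) == 0L || length(ff$consumers) == 0L) {
      stop(sprintf(
        "balanced metabolite '%s' needs at least one producer and one consumer (found %d / %d)",
        ck, length(ff$producers), length(ff$consumers)), call. = FALSE)
    }
  }
  map
}

#' Read a metabolic map from a JSON definition file
#'
#' The file holds `metabolites`, `balanced`, and `modules[{name, genes,
#' consumes, produces, note}]`. Validation errors name the offending record.
#'
#' @param path path to a JSON map definition.
#' @return A validated [metabolic_map()].
#' @export
read_metabolic_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("map file does not parse as JSON: ",
                                           conditionMessage(e), call. = FALSE))
  for (field in c("metabolites", "modules")) {
    if (is.null(doc[[field]])) {
      stop(sprintf("map file is missing the '%s' field", field), call. = FALSE)
    }
  }
  metabolic_map(
    metabolites = unlist(doc$metabolites),
    modules = doc$modules,
    balanced = unlist(doc$balanced %||% list()),
    name = doc$name[[1]] %||% NULL,
    description = doc$description[[1]] %||% NULL)
}

#' Write a metabolic map to a JSON definition file
#'
#' Inverse of [read_metabolic_map()]: reading the written file yields a map
#' with identical content.
#'
#' @param map a [metabolic_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metabolic_map <- function(map, path) {
  stopifnot(inherits(map, "metabolic_map"))
  doc <- list(
    name = map$name, description = map$description,
    metabolites = map$metabolites, balanced = map$balanced,
    modules = lapply(map$modules, function(m) {
      list(name = m$name, genes = as.list(m$genes),
           consumes = as.list(m$consumes), produces = as.list(m$produces),
           note = m$note)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The bundled cytosolic iron / ROS map
#'
#' Fifteen reaction modules around the cytosolic Fenton reaction: three
#' sources and four sinks of the cytosolic Fe2+ pool, ferritin-mediated
#' storage of the Fe3+ product, and eight modules touching the superoxide
#' and hydrogen peroxide pools (the Fenton reaction consumes both). Balance
#' is imposed on cytosolic Fe2+, superoxide and hydrogen peroxide.
#'
#' @return A [metabolic_map()].
#' @export
default_iron_map <- function() {
  read_metabolic_map(system.file("extdata", "iron_map.json",
                                 package = "fentonflux", mustWork = TRUE))
}

module_names <- function(map) vapply(map$modules, `[[`, character(1), "name")

#' Producers and consumers of a metabolite
#'
#' @param map a [metabolic_map()].
#' @param metabolite metabolite identifier.
#' @return list with character vectors `producers` (modules producing the
#'   metabolite) and `consumers` (modules consuming it); either may be empty
#'   for terminal pools.
#' @export
fin_fout <- function(map, metabolite) {
  stopifnot(inherits(map, "metabolic_map"))
  if (!metabolite %in% map$metabolites) {
    stop("unknown metabolite: ", metabolite, call. = FALSE)
  }
  producers <- character()
  consumers <- character()
  for (m in map$modules) {
    if (metabolite %in% m$produces) producers <- c(producers, m$name)
    if (metabolite %in% m$consumes) consumers <- c(consumers, m$name)
  }
  list(producers = producers, consumers = consumers)
}

#' Signed stoichiometric incidence matrix
#'
#' @param map a [metabolic_map()].
#' @param balanced_only if `TRUE`, keep only the rows of the balanced set.
#' @return a metabolite-by-module matrix with +1 where a module produces a
#'   metabolite, -1 where it consumes it, 0 otherwise.
#' @export
stoich_matrix <- function(map, balanced_only = FALSE) {
  stopifnot(inherits(map, "metabolic_map"))
  mets <- if (balanced_only) map$balanced else map$metabolites
  S <- matrix(0, nrow = length(mets), ncol = length(map$modules),
              dimnames = list(mets, module_names(map)))
  for (m in map$modules) {
    S[intersect(m$produces, mets), m$name] <- 1
    S[intersect(m$consumes, mets), m$name] <- -1
  }
  S
}

#' All genes carried by a map
#'
#' @param map a [metabolic_map()].
#' @return unique character vector of member gene symbols.
#' @export
map_genes <- function(map) {
  stopifnot(inherits(map, "metabolic_map"))
  unique(unlist(lapply(map$modules, `[[`, "genes")))
}

#' Cytosolic iron exit modules
#'
#' The five cytosolic iron exit fluxes: the direct consumers of the
#' cytosolic Fe2+ pool (Fe-S cluster synthesis, heme synthesis, Fe2+ export,
#' Fenton reaction) plus the consumers of the Fe3+ pool the Fenton reaction
#' feeds (ferritin synthesis). The relative Fenton level is the Fenton share
#' of the summed flux of these modules.
#'
#' @param map a [metabolic_map()]; defaults expect the bundled iron map.
#' @param fe2,fe3 identifiers of the ferrous and ferric cytosolic pools.
#' @return character vector of module names.
#' @export
iron_exit_modules <- function(map, fe2 = "cytosolic Fe2+", fe3 = "cytosolic Fe3+") {
  out <- fin_fout(map, fe2)$consumers
  if (fe3 %in% map$metabolites) out <- union(out, fin_fout(map, fe3)$consumers)
  out
}

#' @export
print.metabolic_map <- function(x, ...) {
  cat(sprintf("<metabolic_map> %s\n", x$name))
  cat(sprintf("  %d metabolites (%d balanced), %d modules, %d genes\n",
              length(x$metabolites), length(x$balanced),
              length(x$modules), length(map_genes(x))))
  for (m in x$modules) {
    cat(sprintf("  - %s [%d gene%s]\n", m$name, length(m$genes),
                if (length(m$genes) == 1L) "" else "s"))
  }
  invisible(x)
}
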