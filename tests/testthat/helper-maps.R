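# small maps and cohorts shared across tests

chain_map <- function(genes_per_module = 3L) {
  g <- function(prefix) paste0(prefix, seq_len(genes_per_module))
  metabolic_map(
    metabolites = c("A", "B", "C"), balanced = "B",
    modules = list(
      list(name = "R1", genes = g("R1G"), consumes = character(), produces = "B"),
      list(name = "R2", genes = g("R2G"), consumes = "B", produces = "C")),
    name = "two-module chain")
}

# A -> R1 -> B -> {R2, R3} with B balanced: one source, two sinks
fork_map <- function() {
  metabolic_map(
    metabolites = c("A", "B", "C", "D"), balanced = "B",
    modules = list(
      list(name = "R1", genes = c("F1", "F2"), consumes = character(), produces = "B"),
      list(name = "R2", genes = c("F3", "F4"), consumes = "B", produces = "C"),
      list(name = "R3", genes = c("F5", "F6"), consumes = "B", produces = "D")),
    name = "fork")
}

expect_balanced <- function(flux, map, slack = 0.01) {
  Sb <- stoich_matrix(map, balanced_only = TRUE)
  influx <- pmax(Sb, 0) %*% flux
  resid <- abs(Sb %*% flux)
  expect_true(all(resid <= pmax(slack * influx, 1e-6)))
}
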