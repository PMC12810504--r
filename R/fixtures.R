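# Packaged worked-example fixtures: the published 14-gene MDD-drug
# interaction hub table, a frozen 31-edge realization of its degree
# sequence, and the 11-regulon TF table. Shipped as plain-text files under
# inst/extdata and materialized into a working directory on demand.

fixture_file <- function(name) {
  p <- system.file("extdata", name, package = "netpharm")
  if (!nzchar(p)) np_stop("packaged fixture '%s' not found", name)
  p
}

#' The published hub table of the 14-gene MDD-drug network
#'
#' Per-gene degree, normalized betweenness and closeness centrality as
#' printed for the integrated disease-drug interaction network (14 nodes,
#' 31 edges).
#'
#' @return data.frame (`gene`, `name`, `degree`, `betweenness`, `closeness`)
#' @export
fixture_hub_table <- function() {
  read.delim(fixture_file("hub_table_14.tsv"), colClasses = c(
    gene = "character", name = "character", degree = "integer",
    betweenness = "numeric", closeness = "numeric"))
}

#' The 14 genes shared between the disease set and all three drugs
#'
#' @return character vector of 14 gene symbols
#' @export
fixture_shared_genes <- function() {
  fixture_hub_table()$gene
}

#' Frozen 31-edge realization of the published degree sequence
#'
#' A simple undirected graph on the 14 fixture genes whose degree sequence
#' matches the published hub table exactly. The wiring was fixed once (the
#' published edge list itself is not available) and is shipped as a static
#' edge table so wiring-dependent statistics are reproducible.
#'
#' @return undirected igraph with 14 nodes and 31 edges
#' @export
fixture_network <- function() {
  build_network(fixture_file("ppi_edges_14.tsv"), dialect = "tsv")
}

#' Packaged TF-regulon worked example (11 regulators)
#'
#' The published TF-to-target rows for the hub regulation analysis, in
#' TRRUST dialect.
#'
#' @return list of regulons (see [load_trrust()])
#' @export
fixture_tf_table <- function() {
  load_trrust(fixture_file("tf_table.tsv"))
}

#' Materialize all packaged fixtures into a directory
#'
#' Copies the hub table, the frozen edge realization, the TF table and the
#' 14-gene shared set into `dir`.
#'
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
paper_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("hub_table_14.tsv", "ppi_edges_14.tsv", "tf_table.tsv")) {
    file.copy(fixture_file(f), file.path(dir, f), overwrite = TRUE)
  }
  writeLines(fixture_shared_genes(), file.path(dir, "shared_genes_14.txt"))
  invisible(dir)
}
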