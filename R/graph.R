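# Undirected simple-graph construction and the Cytoscape NetworkAnalyzer
# topology panel. igraph is the engine; panel conventions (connected-pairs
# distance statistics, degree-<2 local clustering of 0, population-variance
# heterogeneity) follow NetworkAnalyzer so printed PPI tables are comparable.

#' Build an interaction network from an edge table
#'
#' Reads a 2-column TSV edge list (header optional) or a Cytoscape SIF file
#' (`node relation node [node ...]`, whitespace-separated, one record per
#' line; an interaction fans out from the first node to every node after
#' the relation). The result is an undirected simple igraph: self-loops and
#' duplicate edges are dropped (counts recorded in graph attributes).
#'
#' @param edge_table path to the edge file
#' @param dialect `"tsv"` or `"sif"`
#' @return undirected simple `igraph` with vertex names; graph attributes
#'   `n_self_loops_dropped`, `n_duplicate_edges_dropped`
#' @export
build_network <- function(edge_table, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(edge_table)) np_stop("edge table not found: %s", edge_table)
  lines <- readLines(edge_table, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pairs <- list()
  if (dialect == "tsv") {
    for (i in seq_along(lines)) {
      f <- strsplit(trimws(lines[i]), "\t|\\s+")[[1]]
      if (i == 1L && length(f) >= 2L &&
          all(tolower(f[1:2]) %in% c("source", "target", "node1", "node2",
                                     "from", "to", "genea", "geneb"))) next
      if (length(f) < 2L) np_stop("malformed edge line %d: '%s'", i, lines[i])
      pairs[[length(pairs) + 1L]] <- toupper(f[1:2])
    }
  } else {
    for (i in seq_along(lines)) {
      f <- strsplit(trimws(lines[i]), "\t|\\s+")[[1]]
      if (length(f) == 1L) next  # isolated node record: no edges
      if (length(f) < 3L) np_stop("malformed SIF line %d: '%s'", i, lines[i])
      for (tgt in f[-(1:2)]) pairs[[length(pairs) + 1L]] <- toupper(c(f[1], tgt))
    }
  }
  if (length(pairs) == 0L) np_stop("no edges in %s", edge_table)
  network_from_edges(do.call(rbind, pairs))
}

#' Build an interaction network from an in-memory edge matrix
#'
#' @param edges 2-column character matrix or data.frame of endpoints
#' @return undirected simple `igraph` (see [build_network()])
#' @export
network_from_edges <- function(edges) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  loops <- edges[, 1] == edges[, 2]
  edges <- edges[!loops, , drop = FALSE]
  key <- apply(edges, 1L, function(r) paste(sort(r), collapse = "\r"))
  dups <- duplicated(key)
  edges <- edges[!dups, , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_graph_attr(g, "n_self_loops_dropped", sum(loops))
  igraph::set_graph_attr(g, "n_duplicate_edges_dropped", sum(dups))
}

#' Node degrees
#'
#' @param net igraph network
#' @return named integer vector, sum equals twice the edge count
#' @export
node_degrees <- function(net) {
  d <- igraph::degree(net, loops = FALSE)
  setNames(as.integer(d), names(d))
}

#' Betweenness centrality
#'
#' Exact shortest-path betweenness (endpoints excluded); when
#' `normalized = TRUE` (the convention of printed PPI hub tables) values are
#' divided by `(n-1)(n-2)/2`, the maximum attainable on an undirected graph.
#'
#' @param net igraph network
#' @param normalized divide by the star-graph maximum (default `TRUE`)
#' @return named numeric vector in `[0, 1]` when normalized
#' @export
node_betweenness <- function(net, normalized = TRUE) {
  b <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  n <- igraph::vcount(net)
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    b <- if (denom > 0) b / denom else b * 0
  }
  b
}

#' Closeness centrality
#'
#' Reciprocal of the mean shortest-path distance from a node to the nodes
#' it can reach (Cytoscape NetworkAnalyzer convention: unreachable nodes do
#' not enter the mean; an isolated node scores 0).
#'
#' @param net igraph network
#' @return named numeric vector in `[0, 1]`
#' @export
node_closeness <- function(net) {
  d <- igraph::distances(net)
  diag(d) <- Inf
  apply(d, 1L, function(row) {
    reach <- row[is.finite(row)]
    if (length(reach) == 0L) 0 else 1 / mean(reach)
  })
}

#' Per-node topology metrics (hub table)
#'
#' @param net igraph network
#' @return data.frame `gene`, `degree`, `betweenness`, `closeness`, sorted
#'   by [rank_hubs()] order
#' @export
node_metrics <- function(net) {
  df <- data.frame(gene = igraph::V(net)$name,
                   degree = as.integer(node_degrees(net)),
                   betweenness = as.numeric(node_betweenness(net)),
                   closeness = as.numeric(node_closeness(net)),
                   stringsAsFactors = FALSE)
  rank_hubs(df)
}

#' Rank nodes as candidate hubs
#'
#' Total deterministic order: degree desc, then betweenness desc, then
#' closeness desc, then symbol asc.
#'
#' @param metrics data.frame with `gene`, `degree`, `betweenness`, `closeness`
#' @return the same data.frame, reordered, with a `rank` column
#' @export
rank_hubs <- function(metrics) {
  o <- order(-metrics$degree, -metrics$betweenness, -metrics$closeness, metrics$gene)
  out <- metrics[o, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  out
}

#' Global topology panel
#'
#' The NetworkAnalyzer-style global statistics: node/edge counts, average
#' neighbors, diameter, radius, characteristic path length, clustering
#' coefficient, density, heterogeneity and centralization.
#'
#' Distance statistics are taken over connected ordered pairs only, so the
#' panel stays defined when a removal disconnects the network; the number
#' of connected components is reported alongside. The network clustering
#' coefficient is the mean of local coefficients with degree-<2 nodes
#' contributing 0. Heterogeneity is the coefficient of variation of the
#' degree sequence with population (divide-by-n) variance. Centralization
#' is `(n/(n-2)) * (max_degree/(n-1) - density)`.
#'
#' @param net igraph network with at least 2 nodes
#' @return a `metric_panel`: named list of the panel statistics
#' @export
metric_panel <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) np_stop("metric panel needs at least 2 nodes (got %d)", n)
  e <- igraph::ecount(net)
  deg <- as.numeric(node_degrees(net))
  dens <- 2 * e / (n * (n - 1))
  dmat <- igraph::distances(net)
  finite <- dmat[upper.tri(dmat)]
  finite <- finite[is.finite(finite) & finite > 0]
  ecc <- apply(dmat, 1L, function(row) {
    r <- row[is.finite(row) & row > 0]
    if (length(r) == 0L) NA_real_ else max(r)
  })
  local_cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0  # degree < 2
  mean_deg <- mean(deg)
  het <- if (mean_deg > 0) sqrt(mean((deg - mean_deg)^2)) / mean_deg else 0
  centr <- if (n > 2L) (n / (n - 2)) * (max(deg) / (n - 1) - dens) else 0
  structure(list(
    n_nodes = n,
    n_edges = e,
    avg_neighbors = 2 * e / n,
    diameter = if (length(finite)) max(finite) else NA_real_,
    radius = if (all(is.na(ecc))) NA_real_ else min(ecc, na.rm = TRUE),
    characteristic_path_length = if (length(finite)) mean(finite) else NA_real_,
    clustering_coefficient = mean(local_cc),
    density = dens,
    heterogeneity = het,
    centralization = centr,
    n_components = igraph::count_components(net)
  ), class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  cat("<metric_panel>\n")
  for (m in setdiff(names(x), "n_components")) {
    cat(sprintf("  %-28s %s\n", m,
                if (is.na(x[[m]])) "NA" else format(round(x[[m]], 3))))
  }
  if (x$n_components > 1L) cat(sprintf("  (%d connected components)\n", x$n_components))
  invisible(x)
}

#' Write the hub table and global panel
#'
#' @param net igraph network
#' @param metrics_tsv path for the per-node metrics TSV
#' @param panel_json optional path for the global panel JSON
#' @param digits rounding for the TSV report (default 3, matching published
#'   hub tables); the JSON keeps full precision
#' @return the node-metrics data.frame, invisibly
#' @export
write_topology <- function(net, metrics_tsv, panel_json = NULL, digits = 3L) {
  nm <- node_metrics(net)
  out <- nm
  out$betweenness <- round(out$betweenness, digits)
  out$closeness <- round(out$closeness, digits)
  write_tsv(out, metrics_tsv)
  if (!is.null(panel_json)) write_json(unclass(metric_panel(net)), panel_json)
  invisible(nm)
}
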