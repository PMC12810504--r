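# MCODE molecular-complex detection: vertex weighting by core-clustering
# coefficient, greedy seeded expansion, haircut/fluff post-processing.
# Authored from the published algorithm; deterministic (ties broken by
# symbol order).

subgraph_density <- function(sub) {
  n <- igraph::vcount(sub)
  if (n < 2L) return(0)
  2 * igraph::ecount(sub) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' For each node the closed neighborhood is extracted, its highest k-core
#' located, and the weight set to `k * density(core)` — the core-clustering
#' coefficient scaled by the core number. Dense locally-clustered nodes
#' (clique members) get the largest weights; isolated nodes get 0.
#'
#' @param net igraph network
#' @return named numeric vector of vertex weights
#' @export
mcode_vertex_weights <- function(net) {
  vs <- igraph::V(net)$name
  w <- setNames(numeric(length(vs)), vs)
  for (v in vs) {
    nb <- c(v, names(igraph::neighbors(net, v)))
    sub <- igraph::induced_subgraph(net, nb)
    if (igraph::ecount(sub) == 0L) next
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax < 1L) next
    core_sub <- igraph::induced_subgraph(sub, names(core)[core == kmax])
    w[v] <- kmax * subgraph_density(core_sub)
  }
  w
}

#' MCODE complex score
#'
#' Density times size: `n * 2e / (n (n-1)) = 2e / (n-1)`. A clique Kn
#' scores n.
#'
#' @param n_nodes complex size (>= 2)
#' @param n_edges edges within the complex
#' @return numeric score
#' @export
complex_score <- function(n_nodes, n_edges) {
  if (n_nodes < 2L) np_stop("complex score needs n_nodes >= 2 (got %d)", n_nodes)
  2 * n_edges / (n_nodes - 1)
}

#' Detect molecular complexes (MCODE)
#'
#' Greedy seeded expansion from the highest-weight unassigned vertex:
#' neighbors are recruited while their weight exceeds
#' `seed_weight * (1 - node_score_cutoff)`, breadth-first to `max_depth`.
#' Each vertex belongs to at most one complex. With `haircut` the complex
#' is trimmed to its 2-core (singly-connected members removed); complexes
#' whose densest core falls below `k_core` are discarded. `fluff` optionally
#' adds back boundary neighbors whose closed-neighborhood density exceeds
#' `fluff_density`.
#'
#' @param net igraph network
#' @param node_score_cutoff weight tolerance for expansion (default 0.2)
#' @param k_core minimum core a complex must contain (default 2)
#' @param haircut trim to the 2-core (default `TRUE`)
#' @param fluff add dense boundary neighbors (default `FALSE`)
#' @param fluff_density density threshold for fluff (default 0.2)
#' @param max_depth BFS depth limit from the seed (default 100)
#' @return list of `complex` objects (fields `members`, `seed`, `n_nodes`,
#'   `n_edges`, `score`), sorted score desc, size desc, seed asc
#' @export
find_complexes <- function(net, node_score_cutoff = 0.2, k_core = 2L,
                           haircut = TRUE, fluff = FALSE,
                           fluff_density = 0.2, max_depth = 100L) {
  if (node_score_cutoff < 0 || node_score_cutoff > 1) np_stop("node_score_cutoff must be in [0,1]")
  if (k_core < 1L) np_stop("k_core must be >= 1")
  w <- mcode_vertex_weights(net)
  vs <- names(sort(w, decreasing = TRUE))  # ties: igraph order; re-sorted below
  vs <- vs[order(-w[vs], vs)]              # deterministic: weight desc, symbol asc
  assigned <- character(0)
  complexes <- list()
  for (seed in vs) {
    if (seed %in% assigned || w[seed] <= 0) next
    thresh <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    frontier <- seed
    depth <- 0L
    seen <- seed
    while (length(frontier) > 0L && depth < max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in names(igraph::neighbors(net, v))) {
          if (u %in% seen || u %in% assigned) next
          seen <- c(seen, u)
          if (w[u] > thresh) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(net, members)
    if (haircut && igraph::vcount(sub) > 0L) {
      core <- igraph::coreness(sub)
      keep <- names(core)[core >= 2L]
      if (!(seed %in% keep)) { assigned <- c(assigned, members); next }
      members <- keep
      sub <- igraph::induced_subgraph(net, members)
    }
    if (igraph::vcount(sub) < 2L || max(igraph::coreness(sub)) < k_core) {
      assigned <- c(assigned, members)
      next
    }
    if (fluff) {
      boundary <- setdiff(unique(unlist(lapply(members, function(v)
        names(igraph::neighbors(net, v))))), c(members, assigned))
      add <- boundary[vapply(boundary, function(u) {
        nb <- c(u, names(igraph::neighbors(net, u)))
        subgraph_density(igraph::induced_subgraph(net, nb)) > fluff_density
      }, logical(1))]
      members <- c(members, add)
      sub <- igraph::induced_subgraph(net, members)
    }
    assigned <- c(assigned, members)
    complexes[[length(complexes) + 1L]] <- structure(list(
      members = sort(members),
      seed = seed,
      n_nodes = igraph::vcount(sub),
      n_edges = igraph::ecount(sub),
      score = complex_score(igraph::vcount(sub), igraph::ecount(sub))
    ), class = "complex")
  }
  if (length(complexes) == 0L) return(list())
  o <- order(-vapply(complexes, `[[`, numeric(1), "score"),
             -vapply(complexes, `[[`, numeric(1), "n_nodes"),
             vapply(complexes, `[[`, character(1), "seed"))
  complexes[o]
}

#' @export
print.complex <- function(x, ...) {
  cat(sprintf("<complex> seed=%s nodes=%d edges=%d score=%.3f\n  members: %s\n",
              x$seed, x$n_nodes, x$n_edges, x$score, paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Write detected complexes as TSV (+ optional JSON)
#'
#' @param complexes list from [find_complexes()]
#' @param tsv_path output TSV (rank, seed, n_nodes, n_edges, score, members)
#' @param json_path optional JSON path
#' @return `tsv_path`, invisibly
#' @export
write_complexes <- function(complexes, tsv_path, json_path = NULL) {
  df <- data.frame(
    rank = seq_along(complexes),
    seed = vapply(complexes, `[[`, character(1), "seed"),
    n_nodes = vapply(complexes, `[[`, numeric(1), "n_nodes"),
    n_edges = vapply(complexes, `[[`, numeric(1), "n_edges"),
    score = vapply(complexes, `[[`, numeric(1), "score"),
    members = vapply(complexes, function(cx) paste(cx$members, collapse = ","), character(1))
  )
  write_tsv(df, tsv_path)
  if (!is.null(json_path)) write_json(lapply(complexes, unclass), json_path)
  invisible(tsv_path)
}
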