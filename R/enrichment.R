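# Over-representation analysis: exact hypergeometric (Fisher one-tail)
# tests with fold enrichment and Benjamini-Hochberg FDR, plus kappa-based
# single-linkage clustering of redundant enriched terms.

#' Read a GMT-style annotation table
#'
#' Tab-separated, one term per line: `term_id <tab> description <tab>
#' gene1 <tab> gene2 ...`. An optional `category` can be encoded by
#' prefixing the description as `"CATEGORY|description"`; otherwise every
#' term falls in category `"default"`.
#'
#' @param path GMT file path
#' @return list of annotations, each a list with `term_id`, `term_name`,
#'   `category`, `genes`
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) np_stop("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) np_stop("malformed GMT line %d (need term, description, genes)", i)
    desc <- f[2]
    category <- "default"
    if (grepl("|", desc, fixed = TRUE)) {
      parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
      category <- parts[1]
      desc <- paste(parts[-1], collapse = "|")
    }
    list(term_id = f[1], term_name = desc, category = category,
         genes = unique(normalize_symbols(f[-(1:2)])))
  })
}

#' Hypergeometric over-representation test across an annotation
#'
#' For each term, tests whether the hit list contains more of the term's
#' genes than expected from the universe, with the exact upper-tail
#' hypergeometric probability (one-sided Fisher). Reports fold enrichment
#' `(k/n)/(K/N)` and BH-adjusted FDR computed within each annotation
#' category independently. Terms with fewer than `min_hits` hits are not
#' tested.
#'
#' @param hits gene set of interest (must lie in the universe)
#' @param annotation list of annotations (see [read_gmt()]) or a single-term
#'   list with `term_id`/`genes`
#' @param universe background gene set
#' @param min_hits minimum hits for a term to be tested (default 2)
#' @return data.frame (`term_id`, `term_name`, `category`, `k`, `n`, `K`,
#'   `N`, `fold_enrichment`, `p_value`, `fdr`) sorted by p ascending
#' @export
enrich <- function(hits, annotation, universe, min_hits = 2L) {
  hits <- unique(normalize_symbols(hits))
  universe <- unique(normalize_symbols(universe))
  bad <- setdiff(hits, universe)
  if (length(bad) > 0L) np_stop("hits not in universe: %s", paste(bad, collapse = ", "))
  if (!is.null(annotation$term_id)) annotation <- list(annotation)
  n <- length(hits)
  N <- length(universe)
  rows <- lapply(annotation, function(a) {
    genes <- intersect(a$genes, universe)
    K <- length(genes)
    k <- length(intersect(hits, genes))
    if (K == 0L || k < min_hits) return(NULL)
    data.frame(term_id = a$term_id, term_name = a$term_name %||% a$term_id,
               category = a$category %||% "default",
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      category = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  df <- do.call(rbind, rows)
  df$fdr <- NA_real_
  for (cat in unique(df$category)) {
    sel <- df$category == cat
    df$fdr[sel] <- p.adjust(df$p_value[sel], method = "BH")
  }
  df <- df[order(df$p_value, df$term_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Cohen's kappa between two gene sets over a domain
#'
#' Chance-corrected agreement of the two binary membership vectors over the
#' domain genes: `(po - pe) / (1 - pe)`. When both sets cover the whole
#' domain (or neither covers any of it) agreement is perfect by convention
#' and 1 is returned.
#'
#' @param term_a,term_b gene sets
#' @param domain genes over which membership is compared (at least 2)
#' @return kappa in `[-1, 1]`
#' @export
kappa_similarity <- function(term_a, term_b, domain) {
  domain <- unique(domain)
  if (length(domain) < 2L) np_stop("kappa domain needs at least 2 genes")
  x <- domain %in% term_a
  y <- domain %in% term_b
  po <- mean(x == y)
  pe <- mean(x) * mean(y) + (1 - mean(x)) * (1 - mean(y))
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Cluster enriched terms by kappa similarity
#'
#' Builds the graph linking term pairs with kappa at or above `threshold`
#' (membership vectors restricted to `domain`, by default the hit list —
#' the genes actually tested) and takes its connected components
#' (single-linkage clusters). Each cluster's representative is the member
#' with the smallest p-value (ties: larger term size K, then term_id asc);
#' clusters are sorted by representative p.
#'
#' @param rows data.frame from [enrich()]
#' @param annotation the annotation list the rows were computed from
#' @param threshold kappa threshold (default 0.3)
#' @param domain genes over which kappa is computed; default the hit list
#'   reconstructed from the rows' annotation intersections is not possible,
#'   so pass the hits; falls back to the union of annotated genes
#' @return list of clusters, each with `members` (term_ids), `representative`
#' @export
cluster_terms <- function(rows, annotation, threshold = 0.3, domain = NULL) {
  if (nrow(rows) == 0L) np_stop("no enriched terms to cluster")
  ann <- setNames(lapply(annotation, `[[`, "genes"),
                  vapply(annotation, `[[`, character(1), "term_id"))
  ids <- rows$term_id
  if (is.null(domain)) domain <- unique(unlist(ann[ids]))
  m <- length(ids)
  adj <- diag(TRUE, m)
  if (m > 1L) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      k <- kappa_similarity(ann[[ids[i]]], ann[[ids[j]]], domain)
      adj[i, j] <- adj[j, i] <- (k >= threshold)
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- lapply(unique(comp), function(cid) {
    sel <- which(comp == cid)
    sub <- rows[rows$term_id %in% ids[sel], , drop = FALSE]
    o <- order(sub$p_value, -sub$K, sub$term_id)
    list(members = sort(sub$term_id), representative = sub$term_id[o[1]],
         representative_p = sub$p_value[o[1]])
  })
  clusters[order(vapply(clusters, `[[`, numeric(1), "representative_p"))]
}

#' Write an enrichment table with cluster assignments
#'
#' @param rows data.frame from [enrich()]
#' @param clusters list from [cluster_terms()] (or `NULL` to omit)
#' @param tsv_path output path
#' @return `tsv_path`, invisibly
#' @export
write_enrichment <- function(rows, clusters = NULL, tsv_path) {
  out <- rows
  if (!is.null(clusters)) {
    out$cluster_id <- NA_integer_
    out$representative <- FALSE
    for (i in seq_along(clusters)) {
      sel <- out$term_id %in% clusters[[i]]$members
      out$cluster_id[sel] <- i
      out$representative[out$term_id == clusters[[i]]$representative] <- TRUE
    }
  }
  write_tsv(out, tsv_path)
  invisible(tsv_path)
}
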