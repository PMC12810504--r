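# Multi-source disease-gene evidence: loading, identifier unification and
# the k-of-n retention rule.

#' Load a gene list for one evidence source
#'
#' Reads a plain-text gene list: either one symbol per line, or a 2-column
#' TSV with a header whose second column holds the symbols (first column is
#' taken as a source/annotation label and ignored). Symbols are normalized
#' (uppercase, trimmed) and duplicates collapsed.
#'
#' @param path file path
#' @param source_name label for the evidence source (e.g. "CTD")
#' @return an `evidence_set`: list with `source_name`, `genes` (sorted
#'   character vector) and `n_duplicates_collapsed`
#' @export
load_gene_list <- function(path, source_name) {
  if (!file.exists(path)) np_stop("gene list for source '%s' not found: %s", source_name, path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) np_stop("gene list for source '%s' is empty: %s", source_name, path)
  if (any(grepl("\t", lines, fixed = TRUE))) {
    df <- read.delim(path, header = TRUE, colClasses = "character")
    if (ncol(df) < 2L) np_stop("TSV gene list for source '%s' needs 2 columns", source_name)
    raw <- df[[2L]]
  } else {
    raw <- lines
  }
  evidence_set(raw, source_name)
}

#' Construct an evidence gene set from raw symbols
#'
#' @param genes character vector of raw gene symbols
#' @param source_name source label
#' @return an `evidence_set` (see [load_gene_list()])
#' @export
evidence_set <- function(genes, source_name) {
  if (is.null(source_name) || !nzchar(source_name)) np_stop("source_name must be non-empty")
  norm <- normalize_symbols(genes)
  if (length(norm) == 0L) np_stop("evidence source '%s' has no usable symbols", source_name)
  uniq <- sort(unique(norm))
  structure(
    list(source_name = source_name, genes = uniq,
         n_duplicates_collapsed = length(norm) - length(uniq)),
    class = "evidence_set")
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("<evidence_set> %s: %d genes (%d duplicates collapsed)\n",
              x$source_name, length(x$genes), x$n_duplicates_collapsed))
  invisible(x)
}

#' Resolve gene aliases against a synonym table
#'
#' Replaces every alias by its canonical symbol in each evidence set. When
#' two aliases of the same gene occur in one set they merge, shrinking the
#' set. An alias mapped to two different canonicals is an error.
#'
#' @param sets list of `evidence_set`
#' @param synonym_map data.frame with columns `alias`, `canonical` (or any
#'   2-column frame in that order); `NULL` or empty leaves sets unchanged
#' @return list of `evidence_set` with canonical symbols
#' @export
unify_identifiers <- function(sets, synonym_map = NULL) {
  stopifnot(is.list(sets))
  if (is.null(synonym_map) || nrow(synonym_map) == 0L) return(sets)
  alias <- normalize_symbols(as.character(synonym_map[[1L]]))
  canon <- normalize_symbols(as.character(synonym_map[[2L]]))
  if (length(alias) != length(canon)) np_stop("synonym map has blank entries")
  tab <- unique(data.frame(alias = alias, canonical = canon))
  dup <- tab$alias[duplicated(tab$alias)]
  if (length(dup) > 0L) {
    np_stop("alias mapped to multiple canonicals: %s", paste(unique(dup), collapse = ", "))
  }
  lut <- setNames(tab$canonical, tab$alias)
  lapply(sets, function(s) {
    g <- s$genes
    hit <- g %in% names(lut)
    g[hit] <- lut[g[hit]]
    out <- s
    out$genes <- sort(unique(g))
    out
  })
}

#' Fuse evidence sources under a k-of-n retention rule
#'
#' Retains genes present in at least `min_sources` of the supplied sets —
#' the standard cross-database validation step in network-pharmacology
#' gene assembly (e.g. 2-of-3 across CTD, MalaCards and Open Targets).
#'
#' @param sets list of `evidence_set` (at least `min_sources` of them)
#' @param min_sources minimum number of supporting sources (default 2)
#' @return data.frame with one row per retained gene: `gene`, one logical
#'   column per source, and `support`. Attribute `venn` holds per-region
#'   counts over the full union (regions enumerated for up to 5 sources;
#'   beyond that a support histogram), attribute `union_size` the union size.
#' @export
multi_evidence_intersect <- function(sets, min_sources = 2L) {
  min_sources <- as.integer(min_sources)
  if (min_sources < 1L) np_stop("min_sources must be >= 1")
  if (length(sets) < min_sources) {
    np_stop("min_sources (%d) exceeds number of sources supplied (%d)",
            min_sources, length(sets))
  }
  src <- vapply(sets, function(s) s$source_name, character(1))
  if (anyDuplicated(src)) np_stop("duplicate source names: %s",
                                  paste(src[duplicated(src)], collapse = ", "))
  all_genes <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  member <- vapply(sets, function(s) all_genes %in% s$genes,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(NULL, src))
  support <- rowSums(member)
  mat <- data.frame(gene = all_genes, member, support = as.integer(support),
                    check.names = FALSE)
  venn <- if (length(sets) <= 5L) {
    pattern <- apply(member, 1L, function(r) paste(src[r], collapse = "&"))
    as.list(table(pattern))
  } else {
    as.list(table(factor(support, levels = seq_along(sets))))
  }
  out <- mat[mat$support >= min_sources, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "venn") <- venn
  attr(out, "union_size") <- length(all_genes)
  attr(out, "min_sources") <- min_sources
  out
}

#' Write the retained-gene table and Venn summary of an evidence fusion
#'
#' @param matrix result of [multi_evidence_intersect()]
#' @param tsv_path output TSV (gene, per-source flags, support)
#' @param json_path optional output JSON with Venn-region counts
#' @return `tsv_path`, invisibly
#' @export
write_evidence <- function(matrix, tsv_path, json_path = NULL) {
  write_tsv(matrix, tsv_path)
  if (!is.null(json_path)) {
    write_json(list(venn = attr(matrix, "venn"),
                    union_size = attr(matrix, "union_size"),
                    min_sources = attr(matrix, "min_sources"),
                    n_retained = nrow(matrix)), json_path)
  }
  invisible(tsv_path)
}
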