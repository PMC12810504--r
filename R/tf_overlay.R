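# Transcription-factor regulon overlay: TRRUST-dialect parsing and
# coverage of a key hub set, with a transparent hypergeometric overlap
# statistic against a user-supplied universe.

#' Load a TRRUST-dialect TF-target table
#'
#' Tab-separated, no header, 2-4 columns: TF, target gene, optional mode
#' (Activation/Repression/Unknown), optional literature reference. Rows are
#' aggregated into one regulon per TF; duplicate TF-target pairs collapse.
#'
#' @param path file path
#' @return list of `regulon` objects: `tf`, `targets` (sorted), `modes`
#'   (named by target), `provenance` (named by target)
#' @export
load_trrust <- function(path) {
  if (!file.exists(path)) np_stop("TF table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) np_stop("malformed TF table line %d (need >= 2 columns): '%s'", i, lines[i])
    data.frame(tf = toupper(trimws(f[1])), target = toupper(trimws(f[2])),
               mode = if (length(f) >= 3L) f[3] else "Unknown",
               ref = if (length(f) >= 4L) f[4] else NA_character_)
  })
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("tf", "target")]), , drop = FALSE]
  lapply(split(df, df$tf), function(d) {
    o <- order(d$target)
    structure(list(tf = d$tf[1], targets = d$target[o],
                   modes = setNames(d$mode[o], d$target[o]),
                   provenance = setNames(d$ref[o], d$target[o])),
              class = "regulon")
  })
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s -> %s\n", x$tf, paste(x$targets, collapse = ", ")))
  invisible(x)
}

#' Coverage of a key gene set by transcription-factor regulons
#'
#' For each TF: which key genes it targets, how many network genes it
#' targets, and an upper-tail hypergeometric p for the overlap between the
#' TF's targets and the network genes within the supplied universe.
#' Regulons with no target in the network are excluded. Sorted by number of
#' covered key genes (desc), then p (asc), then TF symbol.
#'
#' @param regulons list from [load_trrust()]
#' @param key_genes the hub set of interest (subset of `network_genes`)
#' @param network_genes genes of the analyzed network (subset of `universe`)
#' @param universe background gene set for the overlap test
#' @return data.frame (`tf`, `covered`, `n_covered`, `k_in_network`,
#'   `n_targets_in_universe`, `p_value`)
#' @export
tf_coverage <- function(regulons, key_genes, network_genes, universe) {
  if (length(key_genes) == 0L) np_stop("key gene set is empty")
  key_genes <- unique(toupper(trimws(key_genes)))
  network_genes <- unique(toupper(trimws(network_genes)))
  universe <- unique(toupper(trimws(universe)))
  if (!all(key_genes %in% network_genes)) {
    np_stop("key genes not in network: %s",
            paste(setdiff(key_genes, network_genes), collapse = ", "))
  }
  if (!all(network_genes %in% universe)) {
    np_stop("network genes not in universe: %s",
            paste(head(setdiff(network_genes, universe), 5), collapse = ", "))
  }
  N <- length(universe)
  K <- length(network_genes)
  rows <- lapply(regulons, function(r) {
    t_u <- intersect(r$targets, universe)
    covered <- intersect(r$targets, key_genes)
    k_net <- length(intersect(t_u, network_genes))
    if (k_net == 0L) return(NULL)
    p <- phyper(k_net - 1, K, N - K, length(t_u), lower.tail = FALSE)
    data.frame(tf = r$tf, covered = paste(sort(covered), collapse = ","),
               n_covered = length(covered), k_in_network = k_net,
               n_targets_in_universe = length(t_u), p_value = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(tf = character(0), covered = character(0),
                      n_covered = integer(0), k_in_network = integer(0),
                      n_targets_in_universe = integer(0), p_value = numeric(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$n_covered, df$p_value, df$tf), , drop = FALSE]
  rownames(df) <- NULL
  df
}
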