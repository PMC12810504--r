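# Seeded synthetic-data generators emulating every input the pipeline
# consumes: multi-source gene lists with controlled overlap, graphs with a
# prescribed degree sequence, planted-clique graphs, annotations with one
# planted enriched term, and TF tables with one planted multi-target
# regulator. Each generator is a pure function of its arguments (seed
# included) and returns the planted truth alongside the data.

synthetic_gene_pool <- function(n, prefix = "G") {
  sprintf("%s%05d", prefix, seq_len(n))
}

#' Generate per-source gene lists with exact planted overlap counts
#'
#' Plants a prescribed number of genes at each support level (present in
#' exactly 1, 2, ... of the `n_sources` lists), assigning each gene's source
#' combination uniformly at random. The truth records every gene's sources.
#'
#' @param exactly named integer vector: count of genes per support level,
#'   names `"1"`, `"2"`, ... up to `n_sources`
#' @param n_sources number of sources (default 3)
#' @param source_names labels (default `S1..Sn`)
#' @param universe_size size of the symbol pool the genes are drawn from;
#'   must hold all planted genes (default: exactly the planted total)
#' @param seed RNG seed
#' @param dir optional directory: one gene-list file per source plus
#'   `truth.json` are written there
#' @return list: `sets` (list of [evidence_set()]), `truth` (data.frame
#'   `gene`, `support`, `sources`), `files` (paths if `dir` given)
#' @export
gen_source_lists <- function(exactly, n_sources = 3L, source_names = NULL,
                             universe_size = NULL, seed = 1L, dir = NULL) {
  n_sources <- as.integer(n_sources)
  lv <- as.integer(names(exactly))
  if (any(is.na(lv)) || any(lv < 1L) || any(lv > n_sources)) {
    np_stop("names of 'exactly' must be support levels in 1..%d", n_sources)
  }
  total <- sum(exactly)
  if (is.null(universe_size)) universe_size <- total
  if (universe_size < total) {
    np_stop("overlap design infeasible: %d planted genes exceed universe of %d",
            total, universe_size)
  }
  if (is.null(source_names)) source_names <- paste0("S", seq_len(n_sources))
  set.seed(seed)
  pool <- synthetic_gene_pool(universe_size)
  genes <- if (total > 0L) sample(pool, total) else character(0)
  support <- rep(lv, times = exactly)
  assign <- lapply(support, function(s) sort(sample.int(n_sources, s)))
  sets_genes <- lapply(seq_len(n_sources), function(j) {
    genes[vapply(assign, function(a) j %in% a, logical(1))]
  })
  truth <- data.frame(
    gene = genes, support = support,
    sources = vapply(assign, function(a) paste(source_names[a], collapse = "&"),
                     character(1)))
  sets <- lapply(seq_len(n_sources), function(j) {
    g <- sets_genes[[j]]
    if (length(g) == 0L) g <- character(0)
    structure(list(source_name = source_names[j], genes = sort(g),
                   n_duplicates_collapsed = 0L), class = "evidence_set")
  })
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(sets, function(s) {
      p <- file.path(dir, paste0(s$source_name, ".txt"))
      writeLines(s$genes, p)
      p
    }, character(1))
    write_json(list(seed = seed, exactly = as.list(exactly),
                    truth = truth), file.path(dir, "truth.json"))
  }
  list(sets = sets, truth = truth, files = files)
}

#' Generate a simple graph with an exactly prescribed degree sequence
#'
#' Realizes the sequence deterministically (Havel-Hakimi style via
#' `igraph::realize_degseq`) and then randomizes the wiring with
#' degree-preserving double edge swaps, so the degrees are exact and the
#' realization varies with the seed. Non-graphical sequences are rejected
#' with the failed Erdos-Gallai condition named.
#'
#' @param sequence integer degree sequence
#' @param seed RNG seed
#' @param names optional vertex names (default `N01..`), assigned in the
#'   order of `sequence`
#' @param n_swaps rewiring attempts (default `10 * edges`)
#' @return undirected simple igraph
#' @export
gen_degree_sequence_graph <- function(sequence, seed = 1L, names = NULL,
                                      n_swaps = NULL) {
  sequence <- as.integer(sequence)
  if (sum(sequence) %% 2L != 0L) np_stop("degree sequence has odd sum %d", sum(sequence))
  if (!igraph::is_graphical(sequence)) {
    np_stop("degree sequence is not graphical (fails the Erdos-Gallai inequalities)")
  }
  set.seed(seed)
  g <- igraph::realize_degseq(sequence)
  if (is.null(n_swaps)) n_swaps <- 10L * igraph::ecount(g)
  if (n_swaps > 0L) {
    g <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  }
  if (is.null(names)) names <- sprintf("N%02d", seq_along(sequence))
  igraph::set_vertex_attr(g, "name", value = names)
}

#' Generate an Erdos-Renyi graph with a planted clique
#'
#' `n` background nodes wired independently with probability `p`, with a
#' clique planted on `clique_size` of them. The truth lists the clique
#' members and flags the degenerate `p = 1` case (clique indistinguishable
#' from background).
#'
#' @param n total number of nodes
#' @param p background edge probability in `[0, 1]`
#' @param clique_size planted clique size (`<= n`)
#' @param seed RNG seed
#' @return list: `net` (igraph), `truth` (list with `clique`, `degenerate`)
#' @export
gen_planted_cluster_graph <- function(n, p, clique_size, seed = 1L) {
  if (p < 0 || p > 1) np_stop("edge probability p must be in [0,1] (got %g)", p)
  if (clique_size > n) np_stop("clique_size %d exceeds n = %d", clique_size, n)
  set.seed(seed)
  nodes <- synthetic_gene_pool(n, "V")
  g <- igraph::sample_gnp(n, p)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  clique <- sort(sample(nodes, clique_size))
  if (clique_size >= 2L) {
    pairs <- t(combn(clique, 2L))
    have <- igraph::get_edge_ids(g, t(pairs), error = FALSE)
    new <- pairs[have == 0, , drop = FALSE]
    if (nrow(new) > 0L) g <- igraph::add_edges(g, t(new))
  }
  list(net = g, truth = list(clique = clique, degenerate = (p == 1)))
}

#' Generate an annotation with one planted enriched term
#'
#' Background terms are drawn uniformly from the universe; the planted term
#' samples its genes without replacement with odds `effect` in favor of the
#' designated hit list, so hits are over-represented in it at a controlled
#' strength.
#'
#' @param universe gene pool
#' @param hits designated hit list (subset of universe)
#' @param n_terms number of background terms
#' @param term_size_range integer range `c(lo, hi)` for term sizes
#' @param planted_size size of the planted term
#' @param effect odds multiplier (> 1) favoring hit genes in the planted term
#' @param seed RNG seed
#' @return list: `annotation` (list usable by [enrich()]), `truth` (list
#'   with `planted_term`, `k_planted`)
#' @export
gen_annotation <- function(universe, hits, n_terms = 20L,
                           term_size_range = c(10L, 50L), planted_size = 30L,
                           effect = 5, seed = 1L) {
  if (effect <= 1) np_stop("planted term effect must exceed 1 (got %g)", effect)
  if (max(term_size_range) > length(universe) || planted_size > length(universe)) {
    np_stop("term sizes exceed the universe")
  }
  if (!all(hits %in% universe)) np_stop("hits must lie in the universe")
  set.seed(seed)
  ann <- lapply(seq_len(n_terms), function(i) {
    sz <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
    list(term_id = sprintf("T%03d", i), term_name = sprintf("background term %d", i),
         category = "default", genes = sample(universe, sz))
  })
  wts <- ifelse(universe %in% hits, effect, 1)
  planted_genes <- sample(universe, planted_size, prob = wts)
  planted <- list(term_id = "PLANTED", term_name = "planted enriched term",
                  category = "default", genes = planted_genes)
  list(annotation = c(ann, list(planted)),
       truth = list(planted_term = "PLANTED",
                    k_planted = length(intersect(hits, planted_genes))))
}

#' Generate a TRRUST-dialect TF table with one planted full-coverage TF
#'
#' Background regulons draw random targets from the universe; the planted
#' TF targets every key gene (plus random extras). Written as a headerless
#' 4-column TSV (TF, target, mode, reference).
#'
#' @param universe gene pool
#' @param key_genes genes the planted TF must cover
#' @param n_tfs number of background TFs
#' @param target_range integer range for background regulon sizes
#' @param planted_tf name of the planted regulator (default `"TF_PLANTED"`)
#' @param max_key_hits_background at most this many key genes per background
#'   regulon (default `length(key_genes) - 1`, so only the planted TF attains
#'   full coverage)
#' @param seed RNG seed
#' @param path optional output TSV path
#' @return list: `regulons` (as from [load_trrust()] when written+read),
#'   `table` (data.frame), `truth`, `path`
#' @export
gen_tf_table <- function(universe, key_genes, n_tfs = 10L,
                         target_range = c(2L, 8L), planted_tf = "TF_PLANTED",
                         max_key_hits_background = NULL, seed = 1L, path = NULL) {
  if (!all(key_genes %in% universe)) np_stop("key genes must lie in the universe")
  if (is.null(max_key_hits_background)) {
    max_key_hits_background <- max(length(key_genes) - 1L, 0L)
  }
  set.seed(seed)
  modes <- c("Activation", "Repression", "Unknown")
  rows <- list()
  if (n_tfs > 0L) {
    for (i in seq_len(n_tfs)) {
      sz <- sample(seq(target_range[1], target_range[2]), 1L)
      tg <- sample(universe, sz)
      keyed <- intersect(tg, key_genes)
      if (length(keyed) > max_key_hits_background) {
        drop <- sample(keyed, length(keyed) - max_key_hits_background)
        tg <- c(setdiff(tg, drop),
                sample(setdiff(universe, c(tg, key_genes)),
                       length(drop)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tf = sprintf("TF%03d", i), target = tg,
        mode = sample(modes, length(tg), replace = TRUE), ref = "synthetic")
    }
  }
  extras <- sample(setdiff(universe, key_genes),
                   min(2L, length(setdiff(universe, key_genes))))
  tg <- c(key_genes, extras)
  rows[[length(rows) + 1L]] <- data.frame(
    tf = planted_tf, target = tg,
    mode = sample(modes, length(tg), replace = TRUE), ref = "synthetic")
  tab <- do.call(rbind, rows)
  out_path <- path
  if (is.null(out_path)) out_path <- tempfile(fileext = ".tsv")
  write.table(tab, out_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(regulons = load_trrust(out_path), table = tab,
       truth = list(planted_tf = planted_tf, key_genes = sort(key_genes)),
       path = out_path)
}
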