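mk_ann <- function(...) {
  terms <- list(...)
  lapply(seq_along(terms), function(i)
    list(term_id = names(terms)[i], term_name = names(terms)[i],
         category = "default", genes = terms[[i]]))
}

test_that("a term equal to the universe is unenriched", {
  universe <- sprintf("G%02d", 1:20)
  hits <- universe[1:5]
  rows <- enrich(hits, mk_ann(ALL = universe), universe)
  expect_equal(rows$fold_enrichment, 1)
  expect_equal(rows$p_value, 1)
})

test_that("the worked 4-of-4 hypergeometric example is exact", {
  universe <- sprintf("G%02d", 1:20)
  hits <- universe[1:5]
  term <- universe[c(1:4)]
  rows <- enrich(hits, mk_ann(T1 = term), universe)
  expect_equal(rows$k, 4L)
  expect_equal(rows$p_value, 16 / 15504, tolerance = 1e-12)
  expect_equal(rows$fold_enrichment, 4)
})

test_that("hits outside the universe are rejected with offenders named", {
  expect_error(enrich(c("A", "ZZZ"), mk_ann(T1 = c("A")), c("A", "B")), "ZZZ")
})

test_that("hypergeometric p equals exhaustive subset enumeration for small N", {
  cases <- expand.grid(N = c(8, 10, 12), n = c(3, 5), K = c(2, 4, 6))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; n <- cases$n[i]; K <- cases$K[i]
    universe <- sprintf("U%02d", 1:N)
    term <- universe[1:K]
    nonterm <- universe[(K + 1):N]
    for (k in max(1, n - length(nonterm)):min(n, K)) {
      hits <- c(term[seq_len(k)], head(nonterm, n - k))
      rows <- enrich(hits, mk_ann(T1 = term), universe, min_hits = 1)
      expect_equal(rows$p_value, oracle_hyper_enum(k, K, N, n), tolerance = 1e-10,
                   label = sprintf("N=%d n=%d K=%d k=%d", N, n, K, k))
    }
  }
})

test_that("BH-FDR is monotone in p-rank, bounded by 1, and at least p", {
  set.seed(5)
  universe <- sprintf("G%03d", 1:200)
  hits <- sample(universe, 30)
  ann <- lapply(1:15, function(i)
    list(term_id = sprintf("T%02d", i), term_name = "t", category = "default",
         genes = sample(universe, sample(10:60, 1))))
  rows <- enrich(hits, ann, universe)
  expect_true(all(diff(rows$fdr) >= -1e-12))
  expect_true(all(rows$fdr <= 1))
  expect_true(all(rows$fdr >= rows$p_value - 1e-12))
})

test_that("FDR is adjusted within annotation categories independently", {
  universe <- sprintf("G%02d", 1:40)
  hits <- universe[1:8]
  ann <- c(
    lapply(1:3, function(i) list(term_id = paste0("BP", i), term_name = "x",
                                 category = "BP", genes = universe[i:(i + 9)])),
    list(list(term_id = "MF1", term_name = "y", category = "MF",
              genes = universe[1:6])))
  rows <- enrich(hits, ann, universe)
  mf <- rows[rows$category == "MF", ]
  expect_equal(mf$fdr, mf$p_value)  # single term in its category
})

test_that("kappa boundary cases match hand-computed 2x2 tables", {
  domain <- sprintf("D%02d", 1:10)
  a <- domain[1:5]
  expect_equal(kappa_similarity(a, a, domain), 1)
  expect_equal(kappa_similarity(a, domain[6:10], domain), -1)
  expect_equal(kappa_similarity(domain, domain, domain), 1)
  # hand case: a=3 both, b=2 only A, c=1 only B, d=4 neither
  A <- domain[1:5]; B <- domain[c(1:3, 6)]
  po <- 7 / 10; pe <- (5 / 10) * (4 / 10) + (5 / 10) * (6 / 10)
  expect_equal(kappa_similarity(A, B, domain), (po - pe) / (1 - pe))
  expect_error(kappa_similarity(a, a, "D1"), "at least 2")
})

test_that("kappa is symmetric and self-agreement is perfect", {
  set.seed(8)
  domain <- sprintf("D%02d", 1:20)
  for (i in 1:10) {
    A <- sample(domain, sample(3:15, 1))
    B <- sample(domain, sample(3:15, 1))
    expect_equal(kappa_similarity(A, B, domain), kappa_similarity(B, A, domain))
    expect_equal(kappa_similarity(A, A, domain), 1)
  }
})

test_that("term clustering: singletons below threshold, merge of identical terms", {
  universe <- sprintf("G%02d", 1:40)
  hits <- universe[1:10]
  ann <- mk_ann(T1 = universe[1:5], T2 = universe[6:10], T3 = universe[c(1:4, 11)])
  rows <- enrich(hits, ann, universe, min_hits = 1)
  # T1 vs T2 disjoint on hits -> negative kappa; T1 vs T3 share 4/5
  cl <- cluster_terms(rows, ann, threshold = 0.3, domain = hits)
  sizes <- vapply(cl, function(x) length(x$members), integer(1))
  expect_equal(sort(sizes), c(1L, 2L))
  big <- cl[[which(sizes == 2)]]
  expect_setequal(big$members, c("T1", "T3"))
  expect_equal(big$representative,
               rows$term_id[which.min(rows$p_value[rows$term_id %in% c("T1", "T3")])])

  ident <- mk_ann(TA = universe[1:6], TB = universe[1:6])
  rows2 <- enrich(hits, ident, universe, min_hits = 1)
  cl2 <- cluster_terms(rows2, ident, domain = hits)
  expect_length(cl2, 1L)
  expect_setequal(cl2[[1]]$members, c("TA", "TB"))
})

test_that("raising the kappa threshold only refines clusters", {
  set.seed(13)
  universe <- sprintf("G%03d", 1:100)
  hits <- sample(universe, 25)
  ann <- lapply(1:8, function(i)
    list(term_id = sprintf("T%d", i), term_name = "t", category = "default",
         genes = sample(universe, 20)))
  rows <- enrich(hits, ann, universe, min_hits = 1)
  if (nrow(rows) >= 2) {
    cl_lo <- cluster_terms(rows, ann, threshold = 0.2, domain = hits)
    cl_hi <- cluster_terms(rows, ann, threshold = 0.5, domain = hits)
    # every high-threshold cluster sits inside one low-threshold cluster
    for (ch in cl_hi) {
      containers <- vapply(cl_lo, function(cl1) all(ch$members %in% cl1$members), logical(1))
      expect_equal(sum(containers), 1L)
    }
  }
})

test_that("two planted term families are recovered as two clusters", {
  set.seed(21)
  universe <- sprintf("G%03d", 1:200)
  hits <- universe[1:40]
  famA_core <- hits[1:18]
  famB_core <- hits[21:38]
  ann <- c(
    lapply(1:3, function(i) list(term_id = paste0("A", i), term_name = "a",
                                 category = "default",
                                 genes = c(famA_core, sample(universe[101:200], 2)))),
    lapply(1:3, function(i) list(term_id = paste0("B", i), term_name = "b",
                                 category = "default",
                                 genes = c(famB_core, sample(universe[101:200], 2)))))
  rows <- enrich(hits, ann, universe)
  cl <- cluster_terms(rows, ann, threshold = 0.3, domain = hits)
  multi <- Filter(function(x) length(x$members) > 1, cl)
  expect_length(multi, 2L)
  fams <- lapply(multi, function(x) sort(substr(x$members, 1, 1)))
  expect_setequal(vapply(fams, function(f) paste(unique(f), collapse = ""), character(1)),
                  c("A", "B"))
})

test_that("a planted enriched term attains the minimum p across seeds", {
  wins <- 0L
  for (seed in 1:100) {
    set.seed(20000 + seed)
    universe <- sprintf("G%04d", 1:1000)
    hits <- sample(universe, 50)
    gen <- gen_annotation(universe, hits, n_terms = 20,
                          term_size_range = c(50L, 150L), planted_size = 100L,
                          effect = 5, seed = seed)
    rows <- enrich(hits, gen$annotation, universe)
    if (nrow(rows) > 0 && rows$term_id[1] == "PLANTED") wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("GMT round-trip preserves terms and categories", {
  p <- withr::local_tempfile(lines = c(
    "T1\tBP|first term\tA\tB\tC",
    "T2\tsecond term\tB\tC"))
  ann <- read_gmt(p)
  expect_equal(ann[[1]]$category, "BP")
  expect_equal(ann[[1]]$genes, c("A", "B", "C"))
  expect_equal(ann[[2]]$category, "default")
  bad <- withr::local_tempfile(lines = "T1\tonly-two-fields")
  expect_error(read_gmt(bad), "line 1")
})
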