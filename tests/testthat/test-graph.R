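test_that("edge tables build clean simple graphs", {
  p <- withr::local_tempfile(lines = c("A\tB", "B\tA", "A\tA"))
  g <- build_network(p, "tsv")
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::graph_attr(g, "n_self_loops_dropped"), 1L)
  expect_equal(igraph::graph_attr(g, "n_duplicate_edges_dropped"), 1L)

  sif <- withr::local_tempfile(lines = c("A pp B C", "D"))
  g2 <- build_network(sif, "sif")
  expect_equal(igraph::ecount(g2), 2L)
  expect_true(igraph::are_adjacent(g2, "A", "B"))
  expect_true(igraph::are_adjacent(g2, "A", "C"))

  bad <- withr::local_tempfile(lines = c("A\tB", "C"))
  expect_error(build_network(bad, "tsv"), "line 2")
})

test_that("degree sum equals twice the edge count on random graphs", {
  for (seed in 1:20) {
    rg <- oracle_random_graph(n = sample(4:12, 1), p = runif(1, 0.2, 0.8), seed = seed)
    if (nrow(rg$edges) == 0) next
    g <- net_from_oracle(rg$edges, rg$nodes)
    expect_equal(sum(node_degrees(g)), 2L * igraph::ecount(g))
  }
})

test_that("betweenness matches small closed forms", {
  g <- network_from_edges(rbind(c("A", "B"), c("B", "C")))
  b <- node_betweenness(g)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))

  star <- network_from_edges(cbind("HUB", paste0("L", 1:4)))
  bs <- node_betweenness(star)
  expect_equal(unname(bs["HUB"]), 1)
  expect_true(all(bs[paste0("L", 1:4)] == 0))
})

test_that("betweenness and closeness equal brute-force enumeration on 100 random graphs", {
  checked <- 0L
  for (seed in 1:100) {
    rg <- oracle_random_graph(n = sample(5:10, 1), p = runif(1, 0.25, 0.7), seed = 1000 + seed)
    if (nrow(rg$edges) < 2) next
    g <- net_from_oracle(rg$edges, rg$nodes)
    vs <- igraph::V(g)$name
    expect_equal(node_betweenness(g)[vs],
                 oracle_betweenness(rg$edges, rg$nodes)[vs], tolerance = 1e-12)
    expect_equal(node_closeness(g)[vs],
                 oracle_closeness(rg$edges, rg$nodes)[vs], tolerance = 1e-12)
    checked <- checked + 1L
  }
  expect_gte(checked, 95L)
})

test_that("closeness of simple paths and stars is exact; isolated nodes score 0", {
  star <- network_from_edges(cbind("HUB", paste0("L", 1:4)))
  expect_equal(unname(node_closeness(star)["HUB"]), 1)

  path <- network_from_edges(rbind(c("A", "B"), c("B", "C")))
  cs <- node_closeness(path)
  expect_equal(unname(cs["A"]), 1 / 1.5)

  g <- igraph::add_vertices(path, 1, name = "LONER")
  expect_equal(unname(node_closeness(g)["LONER"]), 0)
})

test_that("metric panel matches hand-computed values on canonical graphs", {
  k3 <- network_from_edges(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  p <- metric_panel(k3)
  expect_equal(p$density, 1)
  expect_equal(p$clustering_coefficient, 1)
  expect_equal(p$diameter, 1)
  expect_equal(p$heterogeneity, 0)
  expect_equal(p$centralization, 0)

  p4 <- network_from_edges(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  expect_equal(metric_panel(p4)$characteristic_path_length, 5 / 3)

  expect_error(metric_panel(igraph::make_empty_graph(1, directed = FALSE)), "2 nodes")
})

test_that("panel path length equals the BFS oracle on random graphs", {
  for (seed in 1:30) {
    rg <- oracle_random_graph(n = sample(5:10, 1), p = runif(1, 0.3, 0.8), seed = 500 + seed)
    if (nrow(rg$edges) < 2) next
    g <- net_from_oracle(rg$edges, rg$nodes)
    expect_equal(metric_panel(g)$characteristic_path_length,
                 oracle_cpl(rg$edges, rg$nodes), tolerance = 1e-12)
  }
})

test_that("degree-sequence statistics agree between formula and graph on configuration models", {
  seqs <- list(table1_degree_sequence(), c(3, 3, 2, 2, 2), c(4, 3, 3, 2, 2, 2))
  for (s in seqs) for (seed in 1:5) {
    g <- gen_degree_sequence_graph(s, seed = seed)
    p <- metric_panel(g)
    n <- length(s)
    dens <- sum(s) / (n * (n - 1))
    expect_equal(p$density, dens)
    expect_equal(p$avg_neighbors, sum(s) / n)
    expect_equal(p$heterogeneity, sqrt(mean((s - mean(s))^2)) / mean(s))
    expect_equal(p$centralization, (n / (n - 2)) * (max(s) / (n - 1) - dens))
  }
})

test_that("radius <= diameter <= 2*radius and closeness in (0,1] on connected graphs", {
  for (seed in 1:20) {
    g <- gen_degree_sequence_graph(c(4, 3, 3, 3, 3, 2, 2, 2, 2), seed = seed)
    if (igraph::count_components(g) != 1) next
    p <- metric_panel(g)
    expect_lte(p$radius, p$diameter)
    expect_lte(p$diameter, 2 * p$radius)
    cs <- node_closeness(g)
    expect_true(all(cs > 0 & cs <= 1))
  }
})

test_that("hub ranking is total and deterministic", {
  m <- data.frame(gene = c("B", "A", "C"), degree = c(2, 2, 3),
                  betweenness = c(0.5, 0.1, 0.2), closeness = c(0.5, 0.5, 0.9))
  r <- rank_hubs(m)
  expect_equal(r$gene, c("C", "B", "A"))

  ties <- data.frame(gene = c("Z", "M", "A"), degree = 1, betweenness = 0, closeness = 0.5)
  expect_equal(rank_hubs(ties)$gene, c("A", "M", "Z"))
})

test_that("fixture realization has the published degree profile and panel cells", {
  net <- fixture_network()
  expect_equal(igraph::vcount(net), 14L)
  expect_equal(igraph::ecount(net), 31L)
  hub <- fixture_hub_table()
  expect_equal(unname(node_degrees(net)[hub$gene]), hub$degree)
  p <- metric_panel(net)
  expect_equal(round(p$density, 3), 0.341)
  expect_equal(round(p$avg_neighbors, 3), 4.429)
  expect_equal(round(p$heterogeneity, 3), 0.338)
  expect_equal(round(p$centralization, 3), 0.231)
  nm <- node_metrics(net)
  expect_equal(nm$gene[1], "OPRM1")
})
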