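test_that("edge lists are parsed into deduplicated simple graphs", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tA"))
  g <- read_edge_list(f)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 2)

  f2 <- withr::local_tempfile(lines = "A\tA")
  expect_message(g2 <- read_edge_list(f2), "self-loop")
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 1)

  f3 <- withr::local_tempfile(lines = c("A B", "oops"))
  expect_error(read_edge_list(f3), "line 2")
})

test_that("SIF grammar expands one source to many targets", {
  f <- withr::local_tempfile(lines = c("A pp B C", "LONER", "B pp C"))
  g <- read_edge_list(f, dialect = "sif")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "LONER"))
  expect_equal(igraph::ecount(g), 3)  # A-B, A-C, B-C
  expect_equal(igraph::degree(g, "LONER")[[1]], 0)
  f2 <- withr::local_tempfile(lines = "A pp")
  expect_error(read_edge_list(f2, dialect = "sif"), "line 1")
})

test_that("subgraph centrality matches closed forms on canonical graphs", {
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "X"
  expect_equal(subgraph_centrality(iso)$sc, 1)

  k2 <- igraph::make_full_graph(2)
  igraph::V(k2)$name <- c("A", "B")
  expect_equal(subgraph_centrality(k2)$sc, rep(cosh(1), 2), tolerance = 1e-12)

  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("A", "B", "C")
  expect_equal(subgraph_centrality(k3)$sc,
               rep((exp(2) + 2 * exp(-1)) / 3, 3), tolerance = 1e-12)

  expect_error(subgraph_centrality(igraph::make_empty_graph(0)), "empty")
})

test_that("subgraph centrality agrees with the truncated power series", {
  for (s in 1:10) {
    rg <- random_graph(n = sample(4:12, 1), p = 0.4, seed = s)
    ranking <- subgraph_centrality(rg$graph)
    want <- oracle_sc_series(rg$adj)
    expect_equal(ranking$sc, unname(want[ranking$node]), tolerance = 1e-8)
    expect_true(all(diff(ranking$sc) <= 1e-12))   # sorted descending
    expect_true(all(ranking$sc >= 1 - 1e-12))
  }
})

test_that("top-k selection respects centrality order and the tie rule", {
  g <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(2))
  igraph::V(g)$name <- c("T1", "T2", "T3", "P1", "P2")
  rk <- subgraph_centrality(g)
  expect_setequal(top_k_nodes(rk, 3), c("T1", "T2", "T3"))
  expect_setequal(top_k_nodes(rk, 5), igraph::V(g)$name)
  expect_warning(all5 <- top_k_nodes(rk, 10), "exceeds")
  expect_length(all5, 5)

  flat <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(flat)$name <- c("D", "B", "C", "A")
  expect_equal(top_k_nodes(subgraph_centrality(flat), 2), c("A", "B"))
})

test_that("MCODE vertex weights equal core number times core density", {
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "X"
  expect_equal(unname(mcode_vertex_weights(iso)), 0)

  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("A", "B", "C")
  expect_equal(unname(mcode_vertex_weights(k3)), rep(2, 3))  # 2-core, density 1

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- c("A", "B", "C", "D")
  expect_equal(unname(mcode_vertex_weights(k4)), rep(3, 4))  # 3-core, density 1
})

test_that("MCODE recovers dense modules and rejects tree-like pieces", {
  # K4 with a pendant vertex: the single module is the K4, score 1 * 4
  k4p <- igraph::make_full_graph(4)
  igraph::V(k4p)$name <- c("A", "B", "C", "D")
  k4p <- igraph::add_vertices(k4p, 1, name = "P")
  k4p <- igraph::add_edges(k4p, c("A", "P"))
  mods <- mcode_find_modules(k4p, haircut = TRUE)
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$members, c("A", "B", "C", "D"))
  expect_equal(mods[[1]]$score, 4)

  # two disjoint triangles: two modules, each scoring 3
  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  igraph::V(tri2)$name <- c("A1", "A2", "A3", "B1", "B2", "B3")
  mods2 <- mcode_find_modules(tri2)
  expect_length(mods2, 2)
  expect_equal(vapply(mods2, `[[`, numeric(1), "score"), c(3, 3))

  # a path has no 2-core, hence no module
  p3 <- igraph::make_graph(~ A - B - C)
  expect_length(mcode_find_modules(p3), 0)

  expect_error(mcode_find_modules(p3, vwp = 1), "vwp")
})

test_that("MCODE modules partition vertices and always contain a 2-core", {
  rg <- random_graph(n = 25, p = 0.25, seed = 99)
  mods <- mcode_find_modules(rg$graph)
  members <- unlist(lapply(mods, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  for (m in mods) {
    sub <- igraph::induced_subgraph(rg$graph, m$members)
    expect_gte(max(igraph::coreness(sub)), 2)
    expect_gt(m$score, 0)
  }
})

test_that("MCODE output is invariant to node relabeling", {
  rg <- random_graph(n = 15, p = 0.3, seed = 5)
  mods <- mcode_find_modules(rg$graph)
  # relabel nodes reversing the lexicographic order, then map back
  relabel <- setNames(rev(rg$nodes), rg$nodes)
  g2 <- rg$graph
  igraph::V(g2)$name <- unname(relabel[igraph::V(g2)$name])
  mods2 <- mcode_find_modules(g2)
  back <- lapply(mods2, function(m) sort(names(relabel)[match(m$members, relabel)]))
  key <- function(ms) sort(vapply(ms, paste, character(1), collapse = ","))
  expect_equal(key(lapply(mods, `[[`, "members")), key(back))
})

test_that("haircut never grows a module and fluff never shrinks it", {
  # compare modules grown from the same seed vertex (vertex exclusivity makes
  # global totals incomparable across settings)
  for (s in c(17, 23, 29)) {
    rg <- random_graph(n = 20, p = 0.3, seed = s)
    plain <- mcode_find_modules(rg$graph, haircut = FALSE, fluff = FALSE)
    cut <- mcode_find_modules(rg$graph, haircut = TRUE, fluff = FALSE)
    fluffed <- mcode_find_modules(rg$graph, haircut = FALSE, fluff = TRUE)
    by_seed <- function(mods) setNames(mods, vapply(mods, `[[`, character(1), "seed"))
    p <- by_seed(plain); ct <- by_seed(cut); fl <- by_seed(fluffed)
    for (sd in intersect(names(p), names(ct))) {
      expect_lte(length(ct[[sd]]$members), length(p[[sd]]$members))
    }
    sd1 <- names(p)[1]   # first-grown module is unaffected by exclusivity
    if (sd1 %in% names(fl)) {
      expect_gte(length(fl[[sd1]]$members), length(p[[sd1]]$members))
      expect_true(all(p[[sd1]]$members %in% fl[[sd1]]$members))
    }
  }
})

test_that("consensus hubs are the centrality/module intersection", {
  mods <- structure(list(list(members = c("B", "C", "D"), score = 3,
                              seed = "B")), class = "mcode_modules")
  expect_equal(consensus_hubs(c("A", "B", "C"), mods), c("B", "C"))
  expect_equal(consensus_hubs(c("A", "X"), mods), character(0))
  # ordering follows the centrality ranking of the top-k input
  expect_equal(consensus_hubs(c("D", "B"), mods), c("D", "B"))
})

test_that("a planted clique among noise edges is recovered as the hub set", {
  genes <- c(sprintf("BG%02d", 1:40), sprintf("HUB%d", 1:6))
  g <- simulate_gene_network(genes, sprintf("HUB%d", 1:6), p_hub = 1,
                             halo_per_hub = 2, p_noise = 0.01, seed = 31)
  rk <- subgraph_centrality(g)
  hubs <- consensus_hubs(top_k_nodes(rk, 10), mcode_find_modules(g))
  expect_true(all(sprintf("HUB%d", 1:6) %in% hubs))
})
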