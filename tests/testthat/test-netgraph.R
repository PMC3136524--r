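# Graph construction on the glycolysis toy (hand-enumerable) and validation
# of every statistic against brute-force adjacency-matrix oracles.

test_that("bipartite graph has the drawn structure on the glycolysis toy", {
  uni <- glyco_universe()
  g <- build_bipartite(c("HEX1", "PGI", "PFK"), uni)
  types <- igraph::V(g)$type
  expect_equal(sum(types == "reaction"), 3L)
  expect_equal(sum(types == "metabolite"), 7L)
  # PGI reversible: both orientations on both metabolite links
  expect_true(igraph::are_adjacent(g, "M//g6p", "R//PGI"))
  expect_true(igraph::are_adjacent(g, "R//PGI", "M//g6p"))
  expect_true(igraph::are_adjacent(g, "M//f6p", "R//PGI"))
  expect_true(igraph::are_adjacent(g, "R//PGI", "M//f6p"))
  # HEX1 irreversible: one orientation only
  expect_true(igraph::are_adjacent(g, "M//glc-D", "R//HEX1"))
  expect_false(igraph::are_adjacent(g, "R//HEX1", "M//glc-D"))

  single <- build_bipartite("PGI", uni)
  expect_equal(igraph::vcount(single), 3L)
  empty <- build_bipartite(character(0), uni)
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("metabolite graph implements currency removal as drawn", {
  uni <- glyco_universe()
  g <- build_metabolite_graph(c("HEX1", "PGI", "PFK"), uni, glyco_currency)
  expect_setequal(igraph::V(g)$name, c("glc-D", "g6p", "f6p", "fdp"))
  el <- igraph::as_edgelist(g)
  arcs <- paste(el[, 1], el[, 2], sep = ">")
  expect_setequal(arcs, c("glc-D>g6p", "g6p>f6p", "f6p>g6p", "f6p>fdp"))

  # a reaction whose participants are all currency contributes nothing
  uni2 <- make_universe("ATPASE", list(c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)),
                        FALSE, "metabolic")
  g2 <- build_metabolite_graph("ATPASE", uni2, c("atp", "h2o", "adp", "pi", "h"))
  expect_equal(igraph::ecount(g2), 0L)
  expect_equal(igraph::vcount(g2), 0L)

  # empty currency list: arcs between all reactant-product pairs
  g3 <- build_metabolite_graph("HEX1", uni, character(0))
  expect_equal(igraph::ecount(g3), 6L)  # 2 reactants x 3 products
})

test_that("metabolite degrees count distinct reactions, handshake holds", {
  uni <- glyco_universe()
  gt <- c("HEX1", "PGI", "PFK")
  deg <- metabolite_degrees(gt, uni)
  expect_equal(deg[c("atp", "adp", "h", "g6p", "f6p", "glc-D", "fdp")],
               c(atp = 2L, adp = 2L, h = 2L, g6p = 2L, f6p = 2L,
                 `glc-D` = 1L, fdp = 1L))
  expect_false("x" %in% names(deg))
  # handshake: sum of metabolite degrees = sum of reaction degrees
  rdeg <- vapply(uni$stoich[gt], length, integer(1))
  expect_equal(sum(deg), sum(rdeg))
  set.seed(31)
  for (i in 1:10) {
    u <- random_mini_universe()
    gt_i <- sample(metabolic_ids(u), 5)
    expect_equal(sum(metabolite_degrees(gt_i, u)),
                 sum(vapply(u$stoich[gt_i], length, integer(1))))
  }
})

test_that("reaction-degree table stratifies by currency participation", {
  uni <- glyco_universe()
  tab <- reaction_degree_table(uni, glyco_currency)
  # HEX1 and PFK: degree 5 with 3 currency; PGI: degree 2 with 0
  expect_equal(tab$count[tab$degree == 5 & tab$n_currency == 3], 2L)
  expect_equal(tab$count[tab$degree == 2 & tab$n_currency == 0], 1L)
  ex <- make_universe(c("EX_A", "BM"), list(c(A_e = -1), c(A_e = -1)),
                      c(FALSE, FALSE), c("exchange", "biomass"))
  tab2 <- reaction_degree_table(ex, character(0))
  expect_equal(tab2$count[tab2$degree == 1], 2L)
})

test_that("clustering matches the convention on known graphs", {
  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  expect_equal(global_clustering(tri), 1)
  path <- igraph::make_graph(~ a - b, b - c)
  expect_equal(global_clustering(path), 0)
  expect_equal(global_clustering(igraph::make_empty_graph(2)), 0)
  expect_equal(global_clustering(tri, normalization = "triangle_fraction"), 1 / 3)
})

test_that("path statistics and bow tie on the glycolysis metabolite graph", {
  uni <- glyco_universe()
  g <- build_metabolite_graph(c("HEX1", "PGI", "PFK"), uni, glyco_currency)
  ps <- path_stats(g)
  expect_equal(ps$P_C, 7 / 12)
  expect_equal(ps$L, 11 / 7)
  bt <- bow_tie(g)
  expect_identical(bt$LSC, c("f6p", "g6p"))
  expect_identical(bt$IN, "glc-D")
  expect_identical(bt$OUT, "fdp")
  expect_equal(bt$f_bowtie, 1.0)
  expect_equal(bt$f_LSC, 0.5)
})

test_that("degenerate graphs take the documented conventions", {
  two <- igraph::make_empty_graph(2, directed = TRUE)
  igraph::V(two)$name <- c("a", "b")
  ps <- path_stats(two)
  expect_equal(ps$P_C, 0)
  expect_true(is.na(ps$L))
  # complete bidirectional graph: P_C = 1, L = 1
  full <- igraph::make_full_graph(5, directed = TRUE)
  igraph::V(full)$name <- letters[1:5]
  expect_equal(path_stats(full)$P_C, 1)
  expect_equal(path_stats(full)$L, 1)
  # DAG: LSC is a singleton; directed cycle: LSC covers all nodes
  dag <- igraph::graph_from_literal(a - +b, b - +c)
  expect_equal(bow_tie(dag)$f_LSC, 1 / 3)
  cyc <- igraph::make_ring(6, directed = TRUE)
  igraph::V(cyc)$name <- letters[1:6]
  btc <- bow_tie(cyc)
  expect_equal(btc$f_LSC, 1)
  expect_length(btc$IN, 0); expect_length(btc$OUT, 0)
})

test_that("statistics match brute-force oracles on random digraphs", {
  set.seed(77)
  for (i in 1:40) {
    rd <- random_digraph(sample(5:30, 1))
    expect_equal(global_clustering(rd$g), bf_transitivity(rd$adj))
    ps <- path_stats(rd$g); bf <- bf_path_stats(rd$adj)
    expect_equal(ps$P_C, bf$P_C)
    expect_equal(ps$L, bf$L)
    bt <- bow_tie(rd$g); bto <- bf_bowtie(rd$adj, rd$names)
    expect_identical(bt$LSC, bto$LSC)
    expect_identical(bt$IN, bto$IN)
    expect_identical(bt$OUT, bto$OUT)
  }
})

test_that("removing arcs never increases reachability statistics", {
  set.seed(78)
  for (i in 1:10) {
    rd <- random_digraph(15, p = 0.2)
    g <- rd$g
    drop <- sample(igraph::E(g), max(1, igraph::ecount(g) %/% 4))
    sub <- igraph::delete_edges(g, drop)
    expect_lte(path_stats(sub)$P_C, path_stats(g)$P_C + 1e-12)
    expect_lte(bow_tie(sub)$f_LSC, bow_tie(g)$f_LSC + 1e-12)
  }
})

test_that("genotype_stats assembles the per-genotype record", {
  uni <- glyco_universe()
  st <- genotype_stats(c("HEX1", "PGI", "PFK"), uni, glyco_currency,
                       fit_gamma = FALSE)
  expect_equal(st$n_nodes, 4L)
  expect_equal(st$n_arcs, 4L)
  expect_equal(st$P_C, 7 / 12)
  expect_equal(st$L, 11 / 7)
  expect_equal(st$f_bowtie, 1.0)
  expect_true(is.na(st$gamma))  # not requested

  st0 <- genotype_stats(character(0), uni, glyco_currency)
  expect_equal(st0$n_nodes, 0L)
  expect_equal(st0$P_C, 0)

  # P_C >= f_LSC * (|LSC|-1)/(n-1): within-LSC pairs are reachable
  g <- generate_universe(synthetic_universe_spec(n_reactions = 200, seed = 3))
  st2 <- genotype_stats(g$truth$seed_genotype, g$universe, g$currency)
  n <- st2$n_nodes; lsc <- st2$f_LSC * n
  expect_gte(st2$P_C, st2$f_LSC * (lsc - 1) / (n - 1) - 1e-12)
})
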