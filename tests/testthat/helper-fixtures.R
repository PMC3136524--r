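# Shared fixtures: the three-reaction glycolysis toy (HEX1/PGI/PFK), a linear
# FBA chain with a hand-solvable optimum, and brute-force graph oracles.

glyco_universe <- function() {
  make_universe(
    id = c("HEX1", "PGI", "PFK"),
    stoich = list(
      c(`glc-D` = -1, atp = -1, g6p = 1, adp = 1, h = 1),
      c(g6p = -1, f6p = 1),
      c(f6p = -1, atp = -1, fdp = 1, adp = 1, h = 1)),
    reversible = c(FALSE, TRUE, FALSE),
    category = rep("metabolic", 3))
}

glyco_currency <- c("atp", "adp", "h")

# EX_A/T_A scaffold, A -> B conversion (with tunable A coefficient), biomass B ->
chain_universe <- function(coefA = 1) {
  make_universe(
    id = c("EX_A", "T_A", "R1", "BM"),
    stoich = list(
      c(A_e = -1),
      c(A_e = -1, A = 1),
      setNames(c(-coefA, 1), c("A", "B")),
      c(B = -1)),
    reversible = c(FALSE, TRUE, FALSE, FALSE),
    category = c("exchange", "transport", "metabolic", "biomass"))
}

chain_medium <- function(u = 10) medium("A_e", carbon_uptake = u)

# --- brute-force graph oracles (O(n^3), adjacency-matrix based) -------------

# directed adjacency matrix of an igraph object, vertex order = V(g)
adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
}

bf_transitivity <- function(adj_dir) {
  a <- adj_dir | t(adj_dir)
  diag(a) <- FALSE
  n <- nrow(a)
  n_tri <- 0; n_triple <- 0
  for (v in seq_len(n)) {
    nb <- which(a[v, ])
    k <- length(nb)
    if (k < 2) next
    n_triple <- n_triple + k * (k - 1) / 2
    if (k >= 2)
      for (i in seq_len(k - 1)) for (j in (i + 1):k)
        if (a[nb[i], nb[j]]) n_tri <- n_tri + 1
  }
  # n_tri counts each triangle once per corner = 3 times
  if (n_triple == 0) 0 else n_tri / n_triple
}

# all-pairs shortest directed path lengths by repeated BFS
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s; depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) nxt <- c(nxt, which(adj[v, ]))
      nxt <- unique(nxt[!is.finite(d[s, nxt])])
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

bf_path_stats <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(list(L = NA_real_, P_C = 0))
  d <- bf_distances(adj)
  diag(d) <- Inf
  reach <- is.finite(d)
  list(L = if (any(reach)) mean(d[reach]) else NA_real_,
       P_C = sum(reach) / (n * (n - 1)))
}

bf_bowtie <- function(adj, names) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  reach <- is.finite(d)
  mutual <- reach & t(reach)
  comp <- rep(0L, n); cid <- 0L
  for (v in seq_len(n)) if (comp[v] == 0L) {
    cid <- cid + 1L
    comp[mutual[v, ]] <- cid
  }
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(ci) min(names[comp == ci]), character(1))
    best <- best[order(firsts)][1L]
  }
  lsc <- which(comp == best)
  IN <- setdiff(which(apply(reach[, lsc, drop = FALSE], 1, any)), lsc)
  OUT <- setdiff(which(apply(reach[lsc, , drop = FALSE], 2, any)), lsc)
  list(LSC = sort(names[lsc]), IN = sort(names[IN]), OUT = sort(names[OUT]),
       f_LSC = length(lsc) / n,
       f_bowtie = (length(lsc) + length(IN) + length(OUT)) / n)
}

random_digraph <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.03, 0.3)
  adj <- matrix(runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  names <- sprintf("v%02d", seq_len(n))
  el <- which(adj, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = names[el[, 1]], to = names[el[, 2]]),
    directed = TRUE, vertices = data.frame(name = names))
  list(g = g, adj = adj, names = names)
}

# small random universes for property tests (no scaffold, metabolic only)
random_mini_universe <- function(n_rxn = 8, n_met = 10) {
  mets <- sprintf("m%02d", seq_len(n_met))
  stoich <- lapply(seq_len(n_rxn), function(i) {
    k <- sample(2:4, 1)
    picked <- sample(mets, k)
    ns <- sample(seq_len(k - 1), 1)
    setNames(c(rep(-1, ns), rep(1, k - ns)), picked)
  })
  make_universe(sprintf("r%02d", seq_len(n_rxn)), stoich,
                runif(n_rxn) < 0.5, rep("metabolic", n_rxn))
}
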