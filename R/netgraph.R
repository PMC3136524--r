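# Graph representations of a genotype's metabolic network and the structural
# statistics used to compare ensembles to a reference organism. Two
# representations: the directed bipartite metabolite/reaction graph, and the
# currency-filtered directed metabolite-metabolite graph (arcs from every
# non-currency reactant to every non-currency product of each reaction;
# reversible reactions contribute arcs in both directions).

#' Build the directed bipartite metabolite-reaction graph
#'
#' Links run metabolite -> reaction for reactants and reaction -> metabolite
#' for products; a reversible reaction carries every link in both directions.
#' Vertices carry a `type` attribute (`"metabolite"` or `"reaction"`).
#'
#' @param genotype metabolic reaction ids (may be empty).
#' @param universe a `metabolic_universe`.
#' @return an igraph directed graph.
#' @export
build_bipartite <- function(genotype, universe) {
  .check_genotype(genotype, universe)
  edges <- character(0)
  mets <- character(0)
  for (r in genotype) {
    st <- universe$stoich[[r]]
    rea <- names(st)[st < 0]
    pro <- names(st)[st > 0]
    rev <- universe$reactions$reversible[match(r, universe$reactions$id)]
    rn <- paste0("R//", r)
    mn_rea <- paste0("M//", rea); mn_pro <- paste0("M//", pro)
    e <- c(rbind(mn_rea, rn), rbind(rn, mn_pro))
    if (rev) e <- c(e, c(rbind(rn, mn_rea), rbind(mn_pro, rn)))
    edges <- c(edges, e)
    mets <- c(mets, rea, pro)
  }
  mets <- unique(mets)
  verts <- c(if (length(mets)) paste0("M//", mets),
             if (length(genotype)) paste0("R//", genotype))
  em <- matrix(edges, ncol = 2L, byrow = TRUE)
  igraph::graph_from_data_frame(
    d = data.frame(from = em[, 1L], to = em[, 2L]),
    directed = TRUE,
    vertices = data.frame(name = as.character(verts),
                          type = rep(c("metabolite", "reaction"),
                                     c(length(mets), length(genotype))),
                          label = c(mets, genotype)))
}

#' Build the currency-filtered directed metabolite graph
#'
#' Per reaction, arcs from every non-currency reactant to every non-currency
#' product; reversible reactions add the reverse arcs. Currency metabolites
#' are removed globally. Self-loops are discarded and parallel arcs from
#' different reactions collapse to one. Nodes are all non-currency metabolites
#' appearing in the genotype's reactions — isolated nodes are kept.
#'
#' @param genotype metabolic reaction ids.
#' @param universe a `metabolic_universe`.
#' @param currency character vector of currency metabolite ids.
#' @return an igraph directed simple graph.
#' @export
build_metabolite_graph <- function(genotype, universe, currency = character()) {
  .check_genotype(genotype, universe)
  from <- character(0); to <- character(0)
  nodes <- character(0)
  for (r in genotype) {
    st <- universe$stoich[[r]]
    keep <- !(names(st) %in% currency)
    rea <- names(st)[st < 0 & keep]
    pro <- names(st)[st > 0 & keep]
    nodes <- c(nodes, names(st)[keep])
    if (length(rea) == 0L || length(pro) == 0L) next
    pairs <- expand.grid(rea, pro, stringsAsFactors = FALSE)
    rev <- universe$reactions$reversible[match(r, universe$reactions$id)]
    from <- c(from, pairs[[1L]]); to <- c(to, pairs[[2L]])
    if (rev) { from <- c(from, pairs[[2L]]); to <- c(to, pairs[[1L]]) }
  }
  nodes <- unique(nodes)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = from, to = to),
    directed = TRUE,
    vertices = data.frame(name = nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Metabolite degrees of a genotype
#'
#' The degree of a metabolite is the number of distinct reactions of the
#' genotype in which it participates as a reactant or product (bipartite
#' representation; a reversible reaction counts once; currency metabolites
#' included).
#'
#' @param genotype metabolic reaction ids.
#' @param universe a `metabolic_universe`.
#' @return named integer vector (metabolite -> degree).
#' @export
metabolite_degrees <- function(genotype, universe) {
  .check_genotype(genotype, universe)
  mets <- unlist(lapply(universe$stoich[genotype], names), use.names = FALSE)
  tab <- table(mets)
  setNames(as.integer(tab), names(tab))
}

#' Reaction-degree table stratified by currency participation
#'
#' The degree of a reaction is the number of distinct metabolites it involves.
#' For each degree, the count of reactions is broken down by how many of those
#' metabolites are currency metabolites.
#'
#' @param universe a `metabolic_universe`.
#' @param currency currency metabolite ids.
#' @param categories which reaction categories to include (default all).
#' @return data.frame with `degree`, `n_currency`, `count`.
#' @export
reaction_degree_table <- function(universe, currency = character(),
                                  categories = REACTION_CATEGORIES) {
  sel <- universe$reactions$category %in% categories
  ids <- universe$reactions$id[sel]
  deg <- vapply(universe$stoich[ids], length, integer(1))
  ncur <- vapply(universe$stoich[ids],
                 function(s) sum(names(s) %in% currency), integer(1))
  agg <- stats::aggregate(list(count = rep(1L, length(deg))),
                          by = list(degree = deg, n_currency = ncur), FUN = sum)
  agg[order(agg$degree, agg$n_currency), , drop = FALSE]
}

#' Global clustering coefficient
#'
#' Computed on the undirected simplification of the graph. The default
#' `"transitivity"` convention is `C = 3 * N_triangle / N_triple` (each
#' triangle closes three connected triples); `"triangle_fraction"` omits the
#' factor 3. Graphs with fewer than 3 nodes or no connected triple have
#' `C = 0` by convention.
#'
#' @param graph an igraph graph (directed graphs are flattened).
#' @param normalization `"transitivity"` (default) or `"triangle_fraction"`.
#' @return clustering coefficient in `[0, 1]`.
#' @export
global_clustering <- function(graph,
                              normalization = c("transitivity", "triangle_fraction")) {
  normalization <- match.arg(normalization)
  if (igraph::vcount(graph) < 3L) return(0)
  und <- igraph::as_undirected(graph, mode = "collapse")
  C <- igraph::transitivity(und, type = "global")
  if (is.nan(C)) return(0)
  if (normalization == "triangle_fraction") C <- C / 3
  C
}

#' Directed path statistics
#'
#' Over ordered pairs of distinct nodes (A, B): `P_C` is the probability that
#' a directed path A -> B exists; `L` is the mean shortest directed path
#' length over the reachable pairs (NA when no pair is reachable).
#'
#' @param graph an igraph directed graph.
#' @return list with `L`, `P_C`, `n_reachable_pairs`.
#' @export
path_stats <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2L) return(list(L = NA_real_, P_C = 0, n_reachable_pairs = 0L))
  d <- igraph::distances(graph, mode = "out")
  diag(d) <- Inf
  reach <- is.finite(d)
  n_pairs <- sum(reach)
  list(L = if (n_pairs > 0) mean(d[reach]) else NA_real_,
       P_C = n_pairs / (n * (n - 1)),
       n_reachable_pairs = n_pairs)
}

#' Bow-tie decomposition of a directed graph
#'
#' The largest strong component (LSC; ties broken toward the component whose
#' lexicographically smallest member is smallest), the IN set (nodes reaching
#' the LSC but outside it) and the OUT set (nodes reachable from the LSC but
#' outside it).
#'
#' @param graph an igraph directed graph with at least one node.
#' @return list with `LSC`, `IN`, `OUT` (character vectors of node names),
#'   `f_LSC` and `f_bowtie` (fractions of all nodes).
#' @export
bow_tie <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  comp <- igraph::components(graph, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(ci)
      min(igraph::V(graph)$name[comp$membership == ci]), character(1))
    best <- best[order(firsts)][1L]
  }
  lsc <- igraph::V(graph)$name[comp$membership == best]
  rep_v <- lsc[1L]
  reach_in <- igraph::subcomponent(graph, rep_v, mode = "in")$name
  reach_out <- igraph::subcomponent(graph, rep_v, mode = "out")$name
  IN <- setdiff(reach_in, lsc)
  OUT <- setdiff(reach_out, lsc)
  list(LSC = sort(lsc), IN = sort(IN), OUT = sort(OUT),
       f_LSC = length(lsc) / n,
       f_bowtie = (length(lsc) + length(IN) + length(OUT)) / n)
}

#' Structural statistics of one genotype
#'
#' Builds the currency-filtered metabolite graph and assembles the clustering
#' coefficient `C`, path statistics `L` and `P_C`, bow-tie fractions `f_LSC`
#' and `f_bowtie`, and the degree-tail exponent `gamma` fitted on the
#' bipartite metabolite degrees (NA when the tail is too short to fit).
#'
#' @param genotype metabolic reaction ids.
#' @param universe a `metabolic_universe`.
#' @param currency currency metabolite ids.
#' @param fit_gamma fit the degree-tail exponent (set `FALSE` to skip the
#'   power-law fit).
#' @return one-row data.frame with `n_nodes`, `n_arcs`, `C`, `L`, `P_C`,
#'   `f_LSC`, `f_bowtie`, `gamma`.
#' @export
genotype_stats <- function(genotype, universe, currency = character(),
                           fit_gamma = TRUE) {
  if (length(genotype) == 0L)
    return(data.frame(n_nodes = 0L, n_arcs = 0L, C = 0, L = NA_real_, P_C = 0,
                      f_LSC = 0, f_bowtie = 0, gamma = NA_real_))
  g <- build_metabolite_graph(genotype, universe, currency)
  ps <- path_stats(g)
  bt <- if (igraph::vcount(g) > 0L) bow_tie(g) else list(f_LSC = 0, f_bowtie = 0)
  gamma <- NA_real_
  if (fit_gamma) {
    deg <- metabolite_degrees(genotype, universe)
    fit <- tryCatch(fit_discrete_power_law(deg), error = function(e) NULL)
    if (!is.null(fit)) gamma <- fit$gamma
  }
  data.frame(n_nodes = igraph::vcount(g), n_arcs = igraph::ecount(g),
             C = global_clustering(g), L = ps$L, P_C = ps$P_C,
             f_LSC = bt$f_LSC, f_bowtie = bt$f_bowtie, gamma = gamma)
}

#' Structural statistics for every genotype of a sample
#'
#' @param genotypes list of genotypes (or an `ensemble_sample`).
#' @param universe a `metabolic_universe`.
#' @param currency currency metabolite ids.
#' @param fit_gamma fit degree-tail exponents per genotype.
#' @return data.frame, one row per genotype (column `genotype` is the index).
#' @export
ensemble_stats <- function(genotypes, universe, currency = character(),
                           fit_gamma = TRUE) {
  if (inherits(genotypes, "ensemble_sample")) genotypes <- genotypes$genotypes
  rows <- lapply(genotypes, genotype_stats, universe = universe,
                 currency = currency, fit_gamma = fit_gamma)
  out <- do.call(rbind, rows)
  cbind(data.frame(genotype = seq_along(genotypes)), out)
}
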