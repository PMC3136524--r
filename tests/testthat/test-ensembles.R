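# Sampling machinery: direct R-ensemble sampling, swap proposals, constraint
# checking, the MCMC chain (uniformity on exhaustively enumerable spaces,
# detailed balance on a toy, reproducibility, nesting).

test_that("direct R sampling is uniform over subsets", {
  uni <- random_mini_universe(n_rxn = 5)
  ids <- metabolic_ids(uni)
  # n = N: only one subset
  s <- sample_R(uni, 5, 3)
  expect_true(all(vapply(s, function(g) setequal(g, ids), logical(1))))
  expect_error(sample_R(uni, 6, 1), "exceeds")
  expect_equal(lengths(sample_R(uni, 0, 2)), c(0L, 0L))

  set.seed(101)
  draws <- sample_R(uni, 3, 20000)
  keys <- vapply(draws, function(g) paste(sort(g), collapse = ","), character(1))
  counts <- table(keys)
  expect_equal(length(counts), choose(5, 3))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("swap proposals are single swaps with a symmetric distribution", {
  pool <- c("a", "b", "c")
  set.seed(7)
  props <- replicate(400, paste(sort(propose_swap(c("a", "b"), pool)), collapse = ","))
  tab <- table(props)
  expect_setequal(names(tab), c("a,c", "b,c"))
  expect_gt(stats::chisq.test(as.vector(tab))$p.value, 0.01)

  # unique swap case
  expect_identical(sort(propose_swap("a", c("a", "b"))), "b")
  expect_error(propose_swap(c("a", "b"), c("a", "b")), "no swap possible")
  expect_error(propose_swap(character(0), pool), "empty")

  # enumeration: P(G -> G') = 1/(|G| * |pool \ G|) for every neighbor pair,
  # and the reverse swap has the same probability
  pool5 <- letters[1:5]
  g <- c("a", "b", "c")
  p_fwd <- 1 / (3 * 2)
  for (drop in g) for (add in setdiff(pool5, g)) {
    g2 <- c(setdiff(g, drop), add)
    p_rev <- 1 / (length(g2) * length(setdiff(pool5, g2)))
    expect_equal(p_fwd, p_rev)
  }
})

test_that("ensemble constraint checks run in nested order", {
  g <- generate_universe(synthetic_universe_spec(n_reactions = 200, seed = 23))
  uni <- g$universe
  seed_g <- g$truth$seed_genotype
  n <- length(seed_g)
  mE <- distinct_metabolite_count(seed_g, uni)
  bl <- find_blocked(uni)

  spec_R <- ensemble_spec("R", uni, n)
  spec_RM <- ensemble_spec("RM", uni, n, max_metabolites = mE)
  spec_uRM <- ensemble_spec("uRM", uni, n, max_metabolites = mE, blocked = bl)
  spec_V1 <- ensemble_spec("uRM-V1", uni, n, max_metabolites = mE,
                           blocked = bl, environments = g$media)

  expect_true(satisfies_ensemble(seed_g, spec_R, uni))
  expect_true(satisfies_ensemble(seed_g, spec_RM, uni))
  expect_true(satisfies_ensemble(seed_g, spec_uRM, uni))
  expect_true(satisfies_ensemble(seed_g, spec_V1, uni))

  # wrong size
  expect_false(satisfies_ensemble(seed_g[-1], spec_R, uni))
  # blocked member fails the pool test at uRM but not RM
  swapped <- c(seed_g[-n], g$truth$planted_blocked[1])
  expect_true(satisfies_ensemble(swapped, spec_RM, uni) ||
                distinct_metabolite_count(swapped, uni) > mE)
  expect_false(satisfies_ensemble(swapped, spec_uRM, uni))
  # missing essential step fails viability
  broken <- c(setdiff(seed_g, g$truth$planted_essential[1]),
              setdiff(spec_V1$pool, seed_g)[1])
  expect_false(satisfies_ensemble(broken, spec_V1, uni))

  expect_error(ensemble_spec("RM", uni, n), "max_metabolites")
  expect_error(ensemble_spec("uRM", uni, n, max_metabolites = mE), "blocked")
  expect_error(ensemble_spec("uRM-V2", uni, n, max_metabolites = mE,
                             blocked = bl, environments = g$media[1]),
               "environments")
  expect_error(ensemble_spec("bogus", uni, n), "unknown ensemble level")
})

test_that("a size-only chain accepts every swap and is reproducible", {
  uni <- random_mini_universe(n_rxn = 12)
  spec <- ensemble_spec("R", uni, 5)
  start <- sort(metabolic_ids(uni)[1:5])
  pars <- chain_params(burn_in = 500, thin = 10, n_save = 50, seed = 99)
  s1 <- run_mcmc(spec, uni, start, pars)
  expect_equal(s1$acceptance_rate, 1.0)
  expect_length(s1$genotypes, 50)
  s2 <- run_mcmc(spec, uni, start, pars)
  expect_identical(s1$genotypes, s2$genotypes)
  s3 <- run_mcmc(spec, uni, start, chain_params(500, 10, 50, seed = 100))
  expect_false(identical(s1$genotypes, s3$genotypes))

  expect_error(run_mcmc(spec, uni, start[-1], pars), "does not satisfy")
})

test_that("chain visits are uniform over an enumerable constrained space", {
  # 10-reaction universe, n = 4, metabolite cap: valid set enumerated by brute
  # force, chain visit frequencies compared by chi-square
  set.seed(55)
  uni <- random_mini_universe(n_rxn = 10, n_met = 12)
  ids <- metabolic_ids(uni)
  cap <- 9L
  combos <- utils::combn(ids, 4, simplify = FALSE)
  valid <- Filter(function(g) distinct_metabolite_count(g, uni) <= cap, combos)
  expect_gt(length(valid), 20)
  expect_lt(length(valid), length(combos))

  spec <- ensemble_spec("RM", uni, 4, max_metabolites = cap)
  start <- valid[[1]]
  s <- run_mcmc(spec, uni, sort(start),
                chain_params(burn_in = 5000, thin = 1000, n_save = 95, seed = 1),
                visit_interval = 50)
  visited <- s$visits
  key_of <- function(g) paste(match(sort(g), spec$pool), collapse = ",")
  expect_setequal(visited$state, vapply(valid, key_of, character(1)))
  counts <- visited$count
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("transition matrix is doubly stochastic over a toy valid set", {
  # pool {a,b,c,d}, n = 2, constraint: genotype must contain "a" (stand-in
  # for any membership constraint). Valid set: {ab, ac, ad}. Enumerate the
  # swap proposals exactly and check the accept-iff-valid transition matrix.
  pool <- c("a", "b", "c", "d")
  valid <- list(c("a", "b"), c("a", "c"), c("a", "d"))
  keys <- vapply(valid, paste, character(1), collapse = "")
  P <- matrix(0, 3, 3, dimnames = list(keys, keys))
  for (i in seq_along(valid)) {
    g <- valid[[i]]
    for (drop in g) for (add in setdiff(pool, g)) {
      g2 <- sort(c(setdiff(g, drop), add))
      p <- 1 / (length(g) * length(setdiff(pool, g)))
      j <- match(paste(g2, collapse = ""), keys)
      if (is.na(j)) P[i, i] <- P[i, i] + p  # rejected: stay
      else P[i, j] <- P[i, j] + p
    }
  }
  expect_equal(rowSums(P), setNames(rep(1, 3), keys))
  expect_equal(colSums(P), setNames(rep(1, 3), keys))  # doubly stochastic
  expect_equal(P, t(P))                                # symmetric chain
})

test_that("saved genotypes of constrained chains re-pass all nested checks", {
  g <- generate_universe(synthetic_universe_spec(n_reactions = 150,
                                                 n_core_metabolites = 60,
                                                 seed = 31))
  uni <- g$universe
  seed_g <- g$truth$seed_genotype
  n <- length(seed_g)
  mE <- distinct_metabolite_count(seed_g, uni) + 3L
  bl <- find_blocked(uni)
  spec_V1 <- ensemble_spec("uRM-V1", uni, n, max_metabolites = mE,
                           blocked = bl, environments = g$media[1])
  s <- run_mcmc(spec_V1, uni, seed_g,
                chain_params(burn_in = 500, thin = 20, n_save = 40, seed = 8))
  spec_R <- ensemble_spec("R", uni, n)
  spec_RM <- ensemble_spec("RM", uni, n, max_metabolites = mE)
  spec_uRM <- ensemble_spec("uRM", uni, n, max_metabolites = mE, blocked = bl)
  for (gt in s$genotypes) {
    expect_true(satisfies_ensemble(gt, spec_V1, uni))
    expect_true(satisfies_ensemble(gt, spec_uRM, uni))
    expect_true(satisfies_ensemble(gt, spec_RM, uni))
    expect_true(satisfies_ensemble(gt, spec_R, uni))
  }
  # necessary reactions are in the core of the sample
  nec <- find_necessary(restrict_universe(uni, spec_V1$pool), g$media[1])
  core <- Reduce(intersect, s$genotypes)
  expect_true(all(nec %in% core))
})

test_that("cached viability equals uncached evaluation", {
  g <- generate_universe(synthetic_universe_spec(n_reactions = 120,
                                                 n_core_metabolites = 50,
                                                 seed = 37))
  uni <- g$universe
  seed_g <- g$truth$seed_genotype
  bl <- find_blocked(uni)
  spec <- ensemble_spec("uRM-V1", uni, length(seed_g),
                        max_metabolites = distinct_metabolite_count(seed_g, uni) + 3L,
                        blocked = bl, environments = g$media[1])
  s <- run_mcmc(spec, uni, seed_g, chain_params(200, 10, 30, seed = 5))
  # the cache can only have returned what is_viable computes directly
  for (gt in s$genotypes[seq(1, 30, by = 6)])
    expect_true(is_viable(gt, uni, g$media[[1]]))
})

test_that("diversity summary reports dissimilarity, usage and core", {
  same <- list(c("a", "b"), c("a", "b"), c("a", "b"))
  d <- diversity_summary(same)
  expect_equal(d$mean_dissimilarity, 0)
  expect_setequal(d$core, c("a", "b"))

  disjoint <- list(c("a", "b"), c("c", "d"))
  d2 <- diversity_summary(disjoint)
  expect_equal(d2$mean_dissimilarity, 1)
  expect_length(d2$core, 0)

  mixed <- list(c("a", "b", "c"), c("b", "c", "d"))
  d3 <- diversity_summary(mixed)
  expect_equal(d3$mean_dissimilarity, 1 / 3)
  expect_setequal(d3$core, c("b", "c"))
  expect_equal(d3$usage[["a"]], 0.5)
  expect_error(diversity_summary(list(c("a"))), "at least two")
})
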