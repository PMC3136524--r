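# The LP engine is validated against boot::simplex (pure-R simplex from the
# recommended boot package) on random flux polytopes, then the FBA layer
# against hand-solvable chains and the synthetic generator's ground truth.

test_that("internal simplex agrees with boot::simplex on random flux LPs", {
  skip_if_not_installed("boot")
  set.seed(1234)
  checked <- 0
  for (trial in 1:40) {
    m <- sample(3:10, 1); n <- sample(m:(m + 12), 1)
    S <- matrix(0, m, n)
    for (j in 1:n) {
      k <- sample(1:min(4, m), 1)
      S[sample(m, k), j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    }
    rev <- runif(n) < 0.5
    l <- ifelse(rev, -runif(n, 1, 10), 0)
    u <- runif(n, 1, 10)
    cc <- rnorm(n)
    mine <- solve_lp(S, cc, l, u)
    # oracle on shifted variables z = x - l >= 0
    b3 <- as.numeric(-S %*% l)
    sgn <- ifelse(b3 < 0, -1, 1)
    o <- try(boot::simplex(a = cc, A1 = diag(n), b1 = u - l,
                           A3 = S * sgn, b3 = b3 * sgn, maxi = TRUE),
             silent = TRUE)
    if (inherits(o, "try-error") || o$solved != 1) next # oracle-side failure
    checked <- checked + 1
    expect_equal(mine$objective, unname(o$value) + sum(cc * l),
                 tolerance = 1e-7 / max(1, abs(unname(o$value))))
  }
  expect_gte(checked, 20)
})

test_that("maximum biomass flux matches hand-derived chain optima", {
  sys <- build_fba_system(chain_universe(), medium = chain_medium(10))
  expect_equal(max_biomass(sys)$objective, 10, tolerance = 1e-9)

  # 2 A -> B halves the yield
  sys2 <- build_fba_system(chain_universe(coefA = 2), medium = chain_medium(10))
  expect_equal(max_biomass(sys2)$objective, 5, tolerance = 1e-9)

  # no uptake allowed: only the zero flux remains
  m0 <- medium("A_e", carbon_uptake = 1e-12)
  sys0 <- build_fba_system(chain_universe(), medium = m0)
  expect_equal(max_biomass(sys0)$objective, 0, tolerance = 1e-9)

  # doubling the uptake bound doubles the optimum on a linear chain
  sys20 <- build_fba_system(chain_universe(), medium = chain_medium(20))
  expect_equal(max_biomass(sys20)$objective, 20, tolerance = 1e-9)
})

test_that("build_fba_system enforces its preconditions and bounds", {
  uni <- chain_universe()
  expect_error(build_fba_system(uni), "exactly one of")
  expect_error(build_fba_system(uni, medium = chain_medium(),
                                open_exchanges = TRUE), "exactly one of")
  nob <- make_universe(
    id = c("EX_A", "R1"), stoich = list(c(A_e = -1), c(A_e = -1, B = 1)),
    reversible = c(FALSE, FALSE), category = c("exchange", "metabolic"))
  expect_error(build_fba_system(nob, open_exchanges = TRUE), "no biomass")

  sys <- build_fba_system(uni, medium = chain_medium(10))
  j <- match("EX_A", sys$rxn_ids)
  expect_equal(sys$lb[j], -10)
  expect_equal(sys$ub[j], 1000)
  sys_open <- build_fba_system(uni, open_exchanges = TRUE)
  expect_equal(sys_open$lb[j], -1000)
})

test_that("flux ranges match hand LPs and detect dead ends", {
  sys <- build_fba_system(chain_universe(), medium = chain_medium(10))
  fr <- flux_range(sys, "R1")
  expect_equal(fr$vmin, 0, tolerance = 1e-9)
  expect_equal(fr$vmax, 10, tolerance = 1e-9)

  # dead-end consumer of an unproducible metabolite
  uni <- make_universe(
    id = c("EX_A", "T_A", "R1", "DEAD", "BM"),
    stoich = list(c(A_e = -1), c(A_e = -1, A = 1), c(A = -1, B = 1),
                  c(X = -1, Y = 1), c(B = -1)),
    reversible = c(FALSE, TRUE, FALSE, TRUE, FALSE),
    category = c("exchange", "transport", "metabolic", "metabolic", "biomass"))
  sys2 <- build_fba_system(uni, open_exchanges = TRUE)
  fr2 <- flux_range(sys2, "DEAD")
  expect_equal(fr2$vmin, 0, tolerance = 1e-9)
  expect_equal(fr2$vmax, 0, tolerance = 1e-9)
  expect_identical(find_blocked(uni), "DEAD")
})

test_that("viability is the sign of the maximal biomass flux", {
  uni <- chain_universe()
  expect_true(is_viable("R1", uni, chain_medium()))
  expect_false(is_viable(character(0), uni, chain_medium()))
  # wrong carbon source: no path to biomass
  expect_false(is_viable("R1", uni, medium("B_e", carbon_uptake = 10)))
})

test_that("blocked detection recovers planted dead ends exactly (ground truth)", {
  for (s in c(5, 6)) {
    g <- generate_universe(synthetic_universe_spec(n_reactions = 220,
                                                   n_deadend_reactions = 15,
                                                   seed = s))
    bl <- find_blocked(g$universe)
    expect_identical(bl, g$truth$planted_blocked)
  }
})

test_that("adding reactions never decreases the biomass optimum", {
  g <- generate_universe(synthetic_universe_spec(n_reactions = 200, seed = 9))
  uni <- g$universe; env <- g$media[[1]]
  seed_g <- g$truth$seed_genotype
  z_seed <- max_biomass(build_fba_system(uni, seed_g, medium = env))$objective
  z_all <- max_biomass(build_fba_system(uni, medium = env))$objective
  expect_gte(z_all, z_seed - 1e-9)
  set.seed(10)
  extra <- sample(setdiff(metabolic_ids(uni), seed_g), 20)
  z_more <- max_biomass(build_fba_system(uni, c(seed_g, extra), medium = env))$objective
  expect_gte(z_more, z_seed - 1e-9)
})

test_that("necessary reactions are the planted unique backbone steps", {
  g <- generate_universe(synthetic_universe_spec(n_reactions = 220,
                                                 n_environments = 2,
                                                 seed = 12))
  bl <- find_blocked(g$universe)
  unb <- restrict_universe(g$universe, setdiff(metabolic_ids(g$universe), bl))
  nec <- find_necessary(unb, g$media)
  expect_identical(nec, g$truth$planted_essential)
  # parallel-route reactions are never necessary
  routes <- grep("^BB_route", metabolic_ids(g$universe), value = TRUE)
  expect_length(intersect(nec, routes), 0)
  # union semantics: environment 2's entry steps only matter for environment 2
  nec1 <- find_necessary(unb, g$media[1])
  expect_true(all(grep("^BB_entry2", nec, value = TRUE) %in% setdiff(nec, nec1)))
})

test_that("seed genotypes are viable and break when an essential step is removed", {
  g <- generate_universe(synthetic_universe_spec(n_reactions = 200, seed = 21))
  seed_g <- g$truth$seed_genotype
  for (env in g$media) expect_true(is_viable(seed_g, g$universe, env))
  ess <- g$truth$planted_essential
  for (r in ess[c(1, length(ess))]) {
    broken <- vapply(g$media, function(env)
      is_viable(setdiff(seed_g, r), g$universe, env), logical(1))
    expect_true(any(!broken))
  }
})
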