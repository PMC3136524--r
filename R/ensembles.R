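# Nested randomization ensembles over a reaction universe:
#   R       fixed reaction count n (uniform subsets, sampled directly)
#   RM      + distinct-metabolite count <= m_E (MCMC)
#   uRM     + pool restricted to unblocked reactions (MCMC)
#   uRM-Vk  + FBA viability on the first k minimal environments (MCMC)
# The reaction-swap proposal is symmetric and a move is accepted iff all
# constraints hold, so every chain targets the uniform distribution over its
# constrained genotype set; the ensembles are nested by construction.

#' Specify a randomization ensemble
#'
#' @param level one of `"R"`, `"RM"`, `"uRM"` or `"uRM-Vk"` (e.g.
#'   `"uRM-V1"`, `"uRM-V10"`).
#' @param universe the reaction universe.
#' @param n_reactions fixed genotype size (the reference organism's n).
#' @param max_metabolites metabolite-count cap m_E (required for `RM` and
#'   beyond).
#' @param blocked character vector of blocked reaction ids, used to restrict
#'   the pool for `uRM` and beyond.
#' @param environments ordered list of [medium()] objects; the first k are
#'   enforced at level `uRM-Vk`.
#' @return object of class `ensemble_spec` with the resolved reaction `pool`.
#' @export
ensemble_spec <- function(level, universe, n_reactions, max_metabolites = NULL,
                          blocked = NULL, environments = list()) {
  stopifnot(is.character(level), length(level) == 1L)
  k <- 0L
  if (grepl("^uRM-V[0-9]+$", level)) k <- as.integer(sub("^uRM-V", "", level))
  else if (!level %in% c("R", "RM", "uRM")) stop("unknown ensemble level ", sQuote(level))
  constrain_m <- level != "R"
  unblocked_pool <- level == "uRM" || k > 0L
  if (constrain_m && is.null(max_metabolites))
    stop("max_metabolites is required at level ", level)
  if (unblocked_pool && is.null(blocked))
    stop("a blocked-reaction set is required at level ", level)
  if (inherits(environments, "medium")) environments <- list(environments)
  if (k > length(environments))
    stop("level ", level, " needs ", k, " environments, got ", length(environments))
  pool <- metabolic_ids(universe)
  if (unblocked_pool) pool <- setdiff(pool, blocked)
  if (n_reactions > length(pool))
    stop("n_reactions (", n_reactions, ") exceeds pool size (", length(pool), ")")
  structure(list(level = level,
                 n_reactions = as.integer(n_reactions),
                 max_metabolites = if (constrain_m) as.integer(max_metabolites) else NA_integer_,
                 pool = pool,
                 environments = if (k > 0L) environments[seq_len(k)] else list(),
                 k = k),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("<ensemble_spec>", x$level, "| n =", x$n_reactions,
      "| m <=", x$max_metabolites, "| pool =", length(x$pool),
      "| environments =", x$k, "\n")
  invisible(x)
}

#' MCMC chain parameters
#'
#' Defaults follow the published protocol: 1e5 attempted swaps of burn-in to
#' erase the start genotype, then 1e6 further steps saving every 1000th
#' genotype (1000 saved genotypes).
#'
#' @param burn_in attempted swaps discarded before sampling.
#' @param thin save interval, in attempted swaps.
#' @param n_save number of genotypes to save.
#' @param seed optional RNG seed applied at chain start.
#' @return object of class `chain_params`.
#' @export
chain_params <- function(burn_in = 1e5, thin = 1e3, n_save = 1e3, seed = NULL) {
  stopifnot(burn_in >= 0, thin >= 1, n_save >= 1)
  structure(list(burn_in = burn_in, thin = thin, n_save = n_save, seed = seed),
            class = "chain_params")
}

#' Sample the R ensemble directly
#'
#' Uniform subsets of exactly `n` metabolic reactions.
#'
#' @param universe the reaction universe.
#' @param n genotype size.
#' @param count number of genotypes.
#' @param pool optional pool of reaction ids (defaults to all metabolic).
#' @return list of genotypes (character vectors).
#' @export
sample_R <- function(universe, n, count, pool = NULL) {
  if (is.null(pool)) pool <- metabolic_ids(universe)
  if (n > length(pool)) stop("n exceeds pool size")
  replicate(count, sort(sample(pool, n)), simplify = FALSE)
}

#' Propose a reaction swap
#'
#' Removes one uniformly chosen member and adds one uniformly chosen
#' non-member from the pool; the proposal distribution is symmetric.
#'
#' @param genotype nonempty character vector of reaction ids.
#' @param pool candidate reaction ids; `pool` minus `genotype` must be
#'   nonempty.
#' @return the modified genotype.
#' @export
propose_swap <- function(genotype, pool) {
  if (length(genotype) == 0L) stop("empty genotype")
  out <- setdiff(pool, genotype)
  if (length(out) == 0L) stop("genotype equals pool: no swap possible")
  drop <- genotype[sample.int(length(genotype), 1L)]
  add <- out[sample.int(length(out), 1L)]
  c(setdiff(genotype, drop), add)
}

#' Check all constraints of an ensemble for one genotype
#'
#' Checks run cheap-to-expensive and short-circuit: size, metabolite cap
#' (`RM` and beyond), pool membership (`uRM` and beyond), FBA viability on
#' every environment (`uRM-Vk`).
#'
#' @param genotype character vector of reaction ids.
#' @param spec an [ensemble_spec()].
#' @param universe the reaction universe.
#' @return logical.
#' @export
satisfies_ensemble <- function(genotype, spec, universe) {
  if (length(genotype) != spec$n_reactions) return(FALSE)
  if (!all(genotype %in% spec$pool)) return(FALSE)
  if (!is.na(spec$max_metabolites) &&
      distinct_metabolite_count(genotype, universe) > spec$max_metabolites)
    return(FALSE)
  for (env in spec$environments)
    if (!is_viable(genotype, universe, env)) return(FALSE)
  TRUE
}

#' Sample an ensemble by reaction-swap MCMC
#'
#' Runs `burn_in` attempted swaps, then `thin * n_save` more, saving the
#' current genotype every `thin` steps. A rejected trial leaves the state
#' unchanged but counts as a step. The acceptance rate is computed over the
#' sampling phase. Viability LP results are cached per genotype so rejected
#' revisits are free. Fully reproducible under `params$seed`.
#'
#' @param spec an [ensemble_spec()].
#' @param universe the reaction universe.
#' @param start a genotype satisfying the spec (the reference organism's
#'   genotype, or the synthetic seed genotype); a start outside the ensemble
#'   is an error, not silently repaired.
#' @param params a [chain_params()].
#' @param visit_interval when > 0, visit frequencies are recorded every that
#'   many attempted swaps during the sampling phase (used for uniformity
#'   diagnostics on small spaces).
#' @return object of class `ensemble_sample`: `spec`, `genotypes` (list of
#'   sorted id vectors), `acceptance_rate`, `start`, `seed`, and optionally
#'   `visits` (data.frame of state keys and counts).
#' @export
run_mcmc <- function(spec, universe, start, params = chain_params(),
                     visit_interval = 0L) {
  if (!is.null(params$seed)) set.seed(params$seed)
  if (!satisfies_ensemble(start, spec, universe))
    stop("start genotype does not satisfy the ensemble constraints")
  pool <- spec$pool
  if (length(start) >= length(pool)) stop("pool exhausted: nothing to swap in")

  met_ids <- unique(unlist(lapply(universe$stoich[pool], names), use.names = FALSE))
  rxn_mets <- lapply(universe$stoich[pool], function(s) match(names(s), met_ids))
  start_idx <- match(start, pool)

  viab_fun <- NULL
  if (spec$k > 0L) {
    cache <- new.env(parent = emptyenv())
    envs <- spec$environments
    viab_fun <- function(members) {
      key <- paste(sort.int(members), collapse = ",")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      gt <- pool[members]
      ok <- TRUE
      for (env in envs) if (!is_viable(gt, universe, env)) { ok <- FALSE; break }
      cache[[key]] <- ok
      ok
    }
  }

  res <- .mcmc_core(rxn_mets, start_idx, length(met_ids),
                    if (is.na(spec$max_metabolites)) -1L else spec$max_metabolites,
                    viab_fun,
                    params$burn_in, params$thin, as.integer(params$n_save),
                    as.integer(visit_interval))

  genotypes <- lapply(seq_len(nrow(res$genotypes)),
                      function(i) pool[res$genotypes[i, ]])
  out <- list(spec = spec, genotypes = genotypes,
              acceptance_rate = res$acceptance_rate,
              start = start, seed = params$seed, params = params)
  if (visit_interval > 0L) {
    keys <- apply(res$visit_states, 1L, paste, collapse = ",")
    out$visits <- data.frame(state = keys, count = res$visit_counts,
                             stringsAsFactors = FALSE)
  }
  structure(out, class = "ensemble_sample")
}

#' @export
print.ensemble_sample <- function(x, ...) {
  cat("<ensemble_sample>", x$spec$level, "|", length(x$genotypes),
      "genotypes | acceptance rate", sprintf("%.3f", x$acceptance_rate), "\n")
  invisible(x)
}

#' Genetic diversity of a sample
#'
#' Mean pairwise dissimilarity over ordered pairs of distinct saved genotypes,
#' per-reaction usage frequencies, and the core set (reactions present in
#' every genotype).
#'
#' @param sample an `ensemble_sample` or a list of at least two genotypes.
#' @return list with `mean_dissimilarity`, `core`, `usage` (named numeric).
#' @export
diversity_summary <- function(sample) {
  genotypes <- if (inherits(sample, "ensemble_sample")) sample$genotypes else sample
  ng <- length(genotypes)
  if (ng < 2L) stop("need at least two genotypes")
  all_ids <- sort(unique(unlist(genotypes, use.names = FALSE)))
  M <- matrix(0, ng, length(all_ids))
  for (i in seq_len(ng)) M[i, match(genotypes[[i]], all_ids)] <- 1
  sizes <- rowSums(M)
  inter <- M %*% t(M)   # |G_i intersect G_j|
  # dissimilarity(G_i, G_j) = |G_j \ G_i| / |G_j|
  dis <- 1 - sweep(inter, 2L, sizes, "/")
  mean_dis <- sum(dis) / (ng * (ng - 1))  # diagonal is exactly zero
  usage <- setNames(colMeans(M), all_ids)
  list(mean_dissimilarity = mean_dis,
       core = all_ids[usage == 1],
       usage = usage)
}
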