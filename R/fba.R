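# Flux balance analysis on top of the internal bounded-variable simplex.
# Conventions: steady state S v = 0; irreversible reactions [0, V], reversible
# [-V, V]; exchange reactions are written as consumption of the external
# species ("x_e ->"), so negative exchange flux is uptake and positive flux is
# secretion. Only the sign of the maximal biomass flux matters for viability.

#' Solve a linear program over a flux polytope
#'
#' Maximizes `obj' v` subject to `S v = 0` and `lb <= v <= ub` with the
#' package's bounded-variable revised simplex. Every bound interval must
#' contain zero (true for all FBA systems built here), which makes `v = 0` a
#' feasible start.
#'
#' @param S stoichiometric matrix (coerced to sparse).
#' @param obj objective coefficient vector.
#' @param lb,ub flux bounds.
#' @param max_iter iteration cap (0 = automatic).
#' @return list with `objective`, `fluxes`, `status` (`"optimal"` or an error
#'   is thrown), `iterations`.
#' @keywords internal
#' @export
solve_lp <- function(S, obj, lb, ub, max_iter = 0L) {
  S <- methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")
  res <- .simplex_fba(S, as.numeric(obj), as.numeric(lb), as.numeric(ub),
                      as.integer(max_iter))
  status <- c("optimal", "iteration_limit", "unbounded", "singular_basis")[res$status + 1L]
  if (status != "optimal")
    stop("LP solver failed with status ", sQuote(status),
         " after ", res$iterations, " iterations")
  if (res$residual > 1e-6)
    stop("LP solution violates steady state (residual ", res$residual, ")")
  list(objective = res$objective, fluxes = res$x, status = status,
       iterations = res$iterations)
}

#' Build an FBA system for a reaction set
#'
#' Assembles the stoichiometric system for `genotype` plus the universe's
#' fixed transport/exchange/biomass scaffold. Bounds follow the medium: the
#' carbon source may be taken up at `carbon_uptake`, inorganics at
#' `inorganic_uptake`, every other external metabolite can only be secreted.
#' With `open_exchanges = TRUE` every exchange is opened in both directions
#' (the most permissive condition, used for blocked-reaction detection).
#'
#' @param universe a `metabolic_universe` with scaffold and biomass.
#' @param genotype metabolic reaction ids to include; `NULL` means all
#'   metabolic reactions of the universe.
#' @param medium a [medium()]; exactly one of `medium` /
#'   `open_exchanges = TRUE` must be given.
#' @param open_exchanges open all exchange reactions to `[-V, V]`.
#' @param V magnitude of the default flux bound (1000).
#' @param verbose report dropped all-zero metabolite rows.
#' @return object of class `fba_system`: `S`, `lb`, `ub`, `rxn_ids`,
#'   `obj_index`, `met_ids`.
#' @export
build_fba_system <- function(universe, genotype = NULL, medium = NULL,
                             open_exchanges = FALSE, V = 1000, verbose = FALSE) {
  if (is.null(medium) == !open_exchanges)
    stop("give exactly one of `medium` or `open_exchanges = TRUE`")
  if (is.na(universe$biomass_id)) stop("no biomass reaction in universe")
  if (is.null(genotype)) genotype <- metabolic_ids(universe) else .check_genotype(genotype, universe)
  ids <- c(genotype, scaffold_ids(universe))
  idx <- match(ids, universe$reactions$id)
  S <- universe$S[, idx, drop = FALSE]
  rev <- universe$reactions$reversible[idx]
  cat_ <- universe$reactions$category[idx]

  lb <- ifelse(rev, -V, 0)
  ub <- rep(V, length(ids))

  is_ex <- cat_ == "exchange"
  if (any(is_ex)) {
    ex_met <- vapply(universe$stoich[ids[is_ex]], function(s) names(s)[1L], character(1))
    ex_sgn <- vapply(universe$stoich[ids[is_ex]], function(s) sign(s[1L]), numeric(1))
    if (open_exchanges) {
      lb[is_ex] <- -V; ub[is_ex] <- V
    } else {
      up <- rep(NA_real_, sum(is_ex))
      up[ex_met == medium$carbon_source] <- medium$carbon_uptake
      up[ex_met %in% medium$inorganics] <- medium$inorganic_uptake
      l <- rep(0, sum(is_ex)); u <- rep(V, sum(is_ex))
      has_up <- !is.na(up)
      # coefficient -1: uptake = negative flux; coefficient +1: uptake = positive
      neg <- ex_sgn < 0
      l[has_up & neg] <- -up[has_up & neg]
      l[!neg] <- -V                      # secretion for +1 convention is negative flux
      u[!neg] <- ifelse(has_up[!neg], up[!neg], 0)
      lb[is_ex] <- l; ub[is_ex] <- u
    }
  }
  # biomass is a sink: forward only
  lb[cat_ == "biomass"] <- 0

  keep <- Matrix::rowSums(S != 0) > 0
  if (verbose && any(!keep))
    message("dropping ", sum(!keep), " metabolite(s) with no reactions")
  S <- S[keep, , drop = FALSE]

  structure(list(S = S, lb = lb, ub = ub, rxn_ids = ids,
                 obj_index = match(universe$biomass_id, ids),
                 met_ids = rownames(S)),
            class = "fba_system")
}

#' Maximum biomass flux of a system
#'
#' @param system an `fba_system`.
#' @return list with `objective` (Z_max), named `fluxes`, `status`.
#' @export
max_biomass <- function(system) {
  obj <- numeric(length(system$rxn_ids))
  obj[system$obj_index] <- 1
  res <- solve_lp(system$S, obj, system$lb, system$ub)
  res$fluxes <- setNames(res$fluxes, system$rxn_ids)
  res
}

#' Feasible flux range of one reaction
#'
#' Two LPs (minimize and maximize the reaction's flux over the steady-state
#' polytope).
#'
#' @param system an `fba_system`.
#' @param reaction_id reaction to probe.
#' @return list with `reaction`, `vmin`, `vmax`.
#' @export
flux_range <- function(system, reaction_id) {
  j <- match(reaction_id, system$rxn_ids)
  if (is.na(j)) stop("reaction ", sQuote(reaction_id), " not in system")
  obj <- numeric(length(system$rxn_ids))
  obj[j] <- 1
  vmax <- solve_lp(system$S, obj, system$lb, system$ub)$objective
  vmin <- -solve_lp(system$S, -obj, system$lb, system$ub)$objective
  list(reaction = reaction_id, vmin = vmin, vmax = vmax)
}

#' FBA viability of a genotype in a medium
#'
#' A genotype is viable iff the maximal biomass flux of its network (genotype
#' plus scaffold) exceeds the threshold `eps` in the given environment.
#'
#' @param genotype metabolic reaction ids.
#' @param universe a `metabolic_universe`.
#' @param medium a [medium()].
#' @param eps viability threshold absorbing LP round-off (1e-6).
#' @return logical.
#' @export
is_viable <- function(genotype, universe, medium, eps = 1e-6) {
  if (length(genotype) == 0L) return(FALSE)
  sys <- build_fba_system(universe, genotype, medium = medium)
  max_biomass(sys)$objective > eps
}

# private LCG stream so probe objectives do not disturb the caller's RNG
.lcg_runif <- function(n, seed = 20110714) {
  x <- seed %% 2^31
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * x + 12345) %% 2^31
    out[i] <- x / 2^31
  }
  out
}

#' Find blocked reactions of a universe
#'
#' A reaction is blocked when it can carry only zero flux in every steady
#' state under all environmental conditions. Zero feasible flux in the most
#' permissive polytope (all exchanges open in both directions) implies zero in
#' every sub-polytope, so blockedness is decided there. Probe FBAs with
#' generic positive objectives first mark every flux-carrying reaction as
#' unblocked; flux variability analysis then decides the remainder, and every
#' LP optimum additionally clears any still-pending reaction seen carrying
#' flux. The result is independent of reaction order.
#'
#' @param universe a `metabolic_universe`.
#' @param tol zero-flux tolerance (1e-9).
#' @param n_probe number of probe FBAs before the FVA sweep.
#' @param verbose log LP counts.
#' @return sorted character vector of blocked metabolic reaction ids.
#' @export
find_blocked <- function(universe, tol = 1e-9, n_probe = 3L, verbose = FALSE) {
  sys <- build_fba_system(universe, open_exchanges = TRUE)
  mids <- metabolic_ids(universe)
  midx <- match(mids, sys$rxn_ids)
  rev <- universe$reactions$reversible[match(mids, universe$reactions$id)]
  pending <- rep(TRUE, length(mids))
  n_lp <- 0L

  clear_from <- function(flux) {
    hit <- abs(flux[midx]) > tol
    pending[pending & hit] <<- FALSE
  }

  w <- .lcg_runif(n_probe * length(sys$rxn_ids))
  for (p in seq_len(n_probe)) {
    obj <- 0.1 + w[(p - 1L) * length(sys$rxn_ids) + seq_along(sys$rxn_ids)]
    # reversible columns get alternating signs across probes to explore both senses
    sgn <- if (p %% 2L == 0L) -1 else 1
    obj[universe$reactions$reversible[match(sys$rxn_ids, universe$reactions$id)]] <-
      sgn * obj[universe$reactions$reversible[match(sys$rxn_ids, universe$reactions$id)]]
    res <- solve_lp(sys$S, obj, sys$lb, sys$ub)
    n_lp <- n_lp + 1L
    clear_from(res$fluxes)
  }

  blocked <- character(0)
  for (k in seq_along(mids)) {
    if (!pending[k]) next
    j <- midx[k]
    obj <- numeric(length(sys$rxn_ids)); obj[j] <- 1
    res <- solve_lp(sys$S, obj, sys$lb, sys$ub); n_lp <- n_lp + 1L
    clear_from(res$fluxes)
    if (res$objective > tol) { pending[k] <- FALSE; next }
    vmin <- 0
    if (rev[k]) {
      res2 <- solve_lp(sys$S, -obj, sys$lb, sys$ub); n_lp <- n_lp + 1L
      clear_from(res2$fluxes)
      vmin <- -res2$objective
    }
    if (abs(vmin) <= tol) {
      blocked <- c(blocked, mids[k])
      pending[k] <- FALSE
    } else pending[k] <- FALSE
  }
  if (verbose) message("find_blocked: ", n_lp, " LPs, ",
                       length(blocked), "/", length(mids), " blocked")
  sort(blocked)
}

#' Find reactions necessary for viability
#'
#' A metabolic reaction is necessary when deleting it from the full unblocked
#' universe abolishes biomass production (Z_max <= eps) in at least one of the
#' given environments; the union over environments is returned. Reactions
#' carrying zero flux in a wild-type optimum of an environment are provably
#' non-necessary there and are skipped.
#'
#' @param universe a `metabolic_universe` already restricted to unblocked
#'   metabolic reactions (see [restrict_universe()]), or any universe whose
#'   full metabolic set should be screened.
#' @param media list of [medium()] objects (at least one).
#' @param eps viability threshold.
#' @param verbose log LP counts.
#' @return sorted character vector of necessary reaction ids.
#' @export
find_necessary <- function(universe, media, eps = 1e-6, verbose = FALSE) {
  if (inherits(media, "medium")) media <- list(media)
  if (length(media) == 0L) stop("at least one environment is required")
  mids <- metabolic_ids(universe)
  necessary <- character(0)
  n_lp <- 0L
  for (env in media) {
    sys <- build_fba_system(universe, medium = env)
    wt <- max_biomass(sys); n_lp <- n_lp + 1L
    if (wt$objective <= eps)
      stop("full universe is not viable on medium ", sQuote(env$carbon_source))
    cand <- setdiff(mids[abs(wt$fluxes[mids]) > 1e-9], necessary)
    for (r in cand) {
      sub <- build_fba_system(universe, setdiff(mids, r), medium = env)
      z <- max_biomass(sub)$objective; n_lp <- n_lp + 1L
      if (z <= eps) necessary <- c(necessary, r)
    }
  }
  if (verbose) message("find_necessary: ", n_lp, " LPs, ",
                       length(necessary), " necessary")
  sort(unique(necessary))
}

#' Restrict a universe to a subset of its metabolic reactions
#'
#' Keeps the scaffold and the given metabolic reactions; used to form the
#' unblocked universe after [find_blocked()].
#'
#' @param universe a `metabolic_universe`.
#' @param keep metabolic reaction ids to retain (e.g. the unblocked set).
#' @return a new `metabolic_universe`.
#' @export
restrict_universe <- function(universe, keep) {
  .check_genotype(keep, universe)
  ids <- universe$reactions$id
  sel <- ids %in% keep | universe$reactions$category != "metabolic"
  make_universe(ids[sel], universe$stoich[sel],
                universe$reactions$reversible[sel],
                universe$reactions$category[sel])
}
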