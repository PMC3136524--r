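# Synthetic reaction universes with planted ground truth. The generator
# emulates the statistical structure of curated reaction databases:
# currency-couple group-transfer reactions (ATP/ADP-like pairs) that give the
# metabolite degree distribution its fat tail and put the reaction-degree mode
# at 4, bulk reactions with at most 3 non-currency participants reusing
# metabolites by preferential attachment, planted dead-end (provably blocked)
# reactions, and a biomass backbone reachable from exchanged nutrients that
# guarantees a viable seed genotype with known essential steps.
#
# Blockedness and essentiality are certain by construction, without any LP:
# dead-end reactions touch fresh metabolites used nowhere else, every bulk
# reaction draws all its non-currency participants from exchangeable core
# metabolites (so it can always carry flux when all exchanges are open), and
# backbone intermediates appear only on the backbone.

#' Specify a synthetic reaction universe
#'
#' @param n_reactions total number of metabolic (swappable) reactions,
#'   including backbone, dead-end and bulk reactions.
#' @param n_currency_pairs number of carrier couples (ATP/ADP analogues).
#' @param n_core_metabolites cap on the exchangeable core metabolite pool the
#'   bulk reactions draw from.
#' @param p_currency_pair probability a bulk reaction carries one carrier
#'   couple.
#' @param p_second_pair probability a couple-carrying reaction carries a
#'   second couple.
#' @param reuse_exponent preferential-attachment strength for core-metabolite
#'   reuse (weight ~ degree^reuse_exponent).
#' @param p_new_met probability a bulk-reaction slot introduces a new core
#'   metabolite while the pool is below its cap.
#' @param n_deadend_reactions planted blocked reactions.
#' @param n_parallel_routes number of biomass precursors with two redundant
#'   production routes (their reactions are never essential).
#' @param n_precursors number of biomass precursors.
#' @param n_environments number of minimal environments (carbon sources), each
#'   with its own essential entry pathway into the backbone.
#' @param entry_len reactions per environment-specific entry pathway.
#' @param p_reversible probability a bulk or dead-end reaction is reversible.
#' @param p_backbone_coproduct probability a backbone step emits a core-pool
#'   byproduct, coupling the planted pathway into the bulk metabolite graph
#'   (as central metabolism feeds bulk metabolism).
#' @param p_backbone_feed probability a bulk reaction consumes one backbone
#'   intermediate as an extra reactant.
#' @param seed_extra bulk reactions added to the backbone to form the seed
#'   genotype.
#' @param seed RNG seed; generation is bit-reproducible under it.
#' @return object of class `synth_spec`.
#' @export
synthetic_universe_spec <- function(n_reactions = 250L,
                                    n_currency_pairs = 6L,
                                    n_core_metabolites = 150L,
                                    p_currency_pair = 0.8,
                                    p_second_pair = 0.2,
                                    reuse_exponent = 1,
                                    p_new_met = 0.5,
                                    n_deadend_reactions = 50L,
                                    n_parallel_routes = 2L,
                                    n_precursors = 8L,
                                    n_environments = 1L,
                                    entry_len = 2L,
                                    p_reversible = 0.4,
                                    p_backbone_coproduct = 0.7,
                                    p_backbone_feed = 0.2,
                                    seed_extra = 40L,
                                    seed = NULL) {
  spec <- list(n_reactions = as.integer(n_reactions),
               n_currency_pairs = as.integer(n_currency_pairs),
               n_core_metabolites = as.integer(n_core_metabolites),
               p_currency_pair = p_currency_pair,
               p_second_pair = p_second_pair,
               reuse_exponent = reuse_exponent,
               p_new_met = p_new_met,
               n_deadend_reactions = as.integer(n_deadend_reactions),
               n_parallel_routes = as.integer(n_parallel_routes),
               n_precursors = as.integer(n_precursors),
               n_environments = as.integer(n_environments),
               entry_len = as.integer(entry_len),
               p_reversible = p_reversible,
               p_backbone_coproduct = p_backbone_coproduct,
               p_backbone_feed = p_backbone_feed,
               seed_extra = as.integer(seed_extra),
               seed = seed)
  stopifnot(spec$n_currency_pairs >= 1, spec$n_precursors >= 1,
            spec$n_parallel_routes <= spec$n_precursors,
            spec$p_currency_pair >= 0, spec$p_currency_pair <= 1,
            spec$entry_len >= 1, spec$n_environments >= 1)
  n_backbone <- spec$n_environments * spec$entry_len +
    spec$n_parallel_routes * 4L + (spec$n_precursors - spec$n_parallel_routes) * 2L
  if (n_backbone + spec$n_deadend_reactions >= spec$n_reactions)
    stop("n_reactions too small for backbone (", n_backbone,
         ") plus dead-end reactions (", spec$n_deadend_reactions, ")")
  structure(spec, class = "synth_spec")
}

#' Generate a synthetic universe with planted ground truth
#'
#' @param spec a [synthetic_universe_spec()].
#' @return list with `universe` (a `metabolic_universe`), `currency`
#'   (character vector), `media` (list of [medium()] per environment), and
#'   `truth` (list `planted_blocked`, `planted_essential`, `seed_genotype`).
#' @export
generate_universe <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)

  cur_a <- sprintf("cur%da", seq_len(spec$n_currency_pairs))
  cur_b <- sprintf("cur%db", seq_len(spec$n_currency_pairs))
  currency <- as.vector(rbind(cur_a, cur_b))

  id <- character(0); stoich <- list(); reversible <- logical(0); category <- character(0)
  add_rxn <- function(rid, st, rev, cat) {
    # force all arguments before touching shared state: evaluating `st` may
    # itself add scaffold reactions (pick_mets -> add_external -> add_rxn)
    force(rid); force(st); force(rev); force(cat)
    id <<- c(id, rid); stoich[[length(stoich) + 1L]] <<- st
    reversible <<- c(reversible, rev); category <<- c(category, cat)
  }
  externals <- character(0)
  add_external <- function(met) {
    # exchange ("met_e ->", uptake = negative flux) plus reversible transport
    if (met %in% externals) return(invisible())
    externals <<- c(externals, met)
    ext <- paste0(met, "_e")
    add_rxn(paste0("EX_", met), setNames(-1, ext), FALSE, "exchange")
    add_rxn(paste0("T_", met), setNames(c(-1, 1), c(ext, met)), TRUE, "transport")
  }

  for (met in currency) add_external(met)

  # exchangeable core metabolite pool with preferential-attachment reuse
  core_mets <- character(0)
  core_deg <- integer(0)
  next_core <- 1L
  pick_mets <- function(k, exclude = character(0)) {
    out <- character(0)
    for (s in seq_len(k)) {
      avail <- setdiff(core_mets, c(out, exclude))
      make_new <- length(core_mets) < spec$n_core_metabolites &&
        (length(avail) == 0L || runif(1) < spec$p_new_met)
      if (make_new) {
        met <- sprintf("met%d", next_core)
        next_core <<- next_core + 1L
        core_mets <<- c(core_mets, met); core_deg <<- c(core_deg, 0L)
        add_external(met)
        out <- c(out, met)
      } else {
        w <- (core_deg[match(avail, core_mets)] + 1)^spec$reuse_exponent
        out <- c(out, avail[sample.int(length(avail), 1L, prob = w)])
      }
    }
    core_deg[match(out, core_mets)] <<- core_deg[match(out, core_mets)] + 1L
    out
  }
  couple_stoich <- function() {
    st <- setNames(numeric(0), character(0))
    if (runif(1) < spec$p_currency_pair) {
      ci <- sample.int(spec$n_currency_pairs, 1L)
      flip <- runif(1) < 0.5
      st <- setNames(c(-1, 1), if (flip) c(cur_b[ci], cur_a[ci]) else c(cur_a[ci], cur_b[ci]))
      if (runif(1) < spec$p_second_pair && spec$n_currency_pairs > 1L) {
        cj <- sample(setdiff(seq_len(spec$n_currency_pairs), ci), 1L)
        flip2 <- runif(1) < 0.5
        st <- c(st, setNames(c(-1, 1),
                             if (flip2) c(cur_b[cj], cur_a[cj]) else c(cur_a[cj], cur_b[cj])))
      }
    }
    st
  }

  backbone <- character(0); essential <- character(0)
  backbone_mets <- character(0)
  # energy couple consumed by backbone steps: cur1a (medium inorganic) -> cur1b
  couple1 <- c(cur_a[1L], cur_b[1L])
  bb_couple <- function() {
    if (runif(1) < 0.5) setNames(c(-1, 1), couple1) else setNames(numeric(0), character(0))
  }
  # byproduct into the exchangeable core pool: backbone steps feed bulk
  # metabolism the way central metabolism does (secretion keeps viability and
  # essentiality arguments intact)
  bb_coproduct <- function(exclude = character(0)) {
    if (runif(1) < spec$p_backbone_coproduct)
      setNames(1, pick_mets(1L, exclude = exclude))
    else setNames(numeric(0), character(0))
  }
  # entry steps are committed (irreversible, like nutrient phosphorylation);
  # interconversion steps are reversible, giving the planted pathway the
  # cycle-rich strongly connected core central metabolism has
  bb_step <- function(rid, from, to, rev) {
    add_rxn(rid, c(setNames(c(-1, 1), c(from, to)), bb_couple(), bb_coproduct()),
            rev, "metabolic")
    backbone <<- c(backbone, rid)
    backbone_mets <<- c(backbone_mets, to)
  }
  carbon <- sprintf("carb%d", seq_len(spec$n_environments))
  for (cs in carbon) add_external(cs)
  for (j in seq_len(spec$n_environments)) {
    prev <- carbon[j]
    for (s in seq_len(spec$entry_len)) {
      nxt <- if (s == spec$entry_len) "core0" else sprintf("ent%d_%d", j, s)
      rid <- sprintf("BB_entry%d_%d", j, s)
      bb_step(rid, prev, nxt, rev = FALSE)
      essential <- c(essential, rid)
      prev <- nxt
    }
  }
  precursors <- sprintf("pre%d", seq_len(spec$n_precursors))
  for (p in seq_len(spec$n_precursors)) {
    if (p <= spec$n_parallel_routes) {
      for (branch in c("a", "b")) {
        mid <- sprintf("alt%d%s", p, branch)
        bb_step(sprintf("BB_route%d%s_1", p, branch), "core0", mid, rev = TRUE)
        bb_step(sprintf("BB_route%d%s_2", p, branch), mid, precursors[p], rev = TRUE)
      }
    } else {
      mid <- sprintf("mid%d", p)
      r1 <- sprintf("BB_trunk%d_1", p); r2 <- sprintf("BB_trunk%d_2", p)
      bb_step(r1, "core0", mid, rev = TRUE)
      bb_step(r2, mid, precursors[p], rev = TRUE)
      essential <- c(essential, r1, r2)
    }
  }
  add_rxn("BIOMASS", setNames(rep(-1, spec$n_precursors), precursors), FALSE, "biomass")
  backbone_mets <- unique(backbone_mets)

  # bulk reactions over the exchangeable core pool; some consume a backbone
  # intermediate (producible whenever exchanges are open, so never blocked)
  n_backbone <- length(backbone)
  n_bulk <- spec$n_reactions - n_backbone - spec$n_deadend_reactions
  bulk <- character(0)
  shape_probs <- c(`1_1` = 0.8, `1_2` = 0.1, `2_1` = 0.1)
  for (b in seq_len(n_bulk)) {
    feed <- runif(1) < spec$p_backbone_feed
    if (feed) {
      nr <- 1L; np <- 1L  # keep <= 3 non-currency participants
    } else {
      shape <- sample(names(shape_probs), 1L, prob = shape_probs)
      nr <- as.integer(substr(shape, 1L, 1L)); np <- as.integer(substr(shape, 3L, 3L))
    }
    rea <- pick_mets(nr)
    pro <- pick_mets(np, exclude = rea)
    st <- c(setNames(rep(-1, nr), rea), setNames(rep(1, np), pro))
    if (feed)
      st <- c(setNames(-1, backbone_mets[sample.int(length(backbone_mets), 1L)]), st)
    rid <- sprintf("BLK%04d", b)
    # a backbone-fed reaction is irreversible: its reverse would produce a
    # backbone intermediate and break the planted-essentiality guarantee
    add_rxn(rid, c(st, couple_stoich()),
            !feed && runif(1) < spec$p_reversible, "metabolic")
    bulk <- c(bulk, rid)
  }

  # planted dead ends: fresh metabolites touched by no other reaction
  deadend <- character(0)
  for (d in seq_len(spec$n_deadend_reactions)) {
    rid <- sprintf("DEAD%03d", d)
    fresh <- sprintf("dead%d", d)
    if (d %% 2L == 0L && length(core_mets) > 0L) {
      src <- core_mets[sample.int(length(core_mets), 1L)]
      st <- setNames(c(-1, 1), c(src, fresh))
    } else {
      fresh2 <- sprintf("dead%db", d)
      st <- setNames(c(-1, 1), c(fresh2, fresh))
    }
    add_rxn(rid, c(st, couple_stoich()), runif(1) < spec$p_reversible, "metabolic")
    deadend <- c(deadend, rid)
  }

  universe <- make_universe(id, stoich, reversible, category)

  media <- lapply(seq_len(spec$n_environments), function(j)
    medium(carbon_source = paste0(carbon[j], "_e"),
           inorganics = paste0(couple1, "_e")))

  seed_genotype <- c(backbone,
                     if (spec$seed_extra > 0L)
                       sort(sample(bulk, min(spec$seed_extra, length(bulk)))))

  list(universe = universe,
       currency = currency,
       media = media,
       truth = list(planted_blocked = sort(deadend),
                    planted_essential = sort(essential),
                    seed_genotype = seed_genotype))
}

#' Modified currency list (robustness check)
#'
#' Ranks the currency metabolites by their degree in the complete universe,
#' ascending (the lowest-degree currency metabolite has rank 1), and removes
#' the `drop_n` smallest-rank entries.
#'
#' @param currency character vector of currency metabolite ids.
#' @param universe the complete reaction universe.
#' @param drop_n number of lowest-degree entries to eliminate
#'   (`drop_n < length(currency)`).
#' @return the reduced currency list, original order preserved.
#' @export
modified_currency_list <- function(currency, universe, drop_n) {
  if (drop_n >= length(currency)) stop("drop_n must be smaller than the list")
  if (drop_n == 0L) return(currency)
  deg <- vapply(currency, function(met)
    sum(vapply(universe$stoich, function(s) met %in% names(s), logical(1))),
    numeric(1))
  ranked <- currency[order(deg, seq_along(currency))]  # ties by list position
  drop <- ranked[seq_len(drop_n)]
  currency[!currency %in% drop]
}
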