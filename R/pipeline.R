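# End-to-end orchestration: blocked filtering -> ensemble sampling ->
# per-genotype structural statistics -> ensemble-vs-reference comparison,
# with fixed TSV/JSON-lines output schemas. Ensemble summaries use the
# population standard deviation (n denominator), as noted in output headers.

.pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

STAT_COLS <- c("n_nodes", "n_arcs", "C", "L", "P_C", "f_LSC", "f_bowtie", "gamma")

#' Run the full randomization pipeline
#'
#' For each requested ensemble level: sample (direct sampling for `R`,
#' reaction-swap MCMC otherwise), compute structural statistics and a
#' degree-tail exponent for every saved genotype, and write per-level
#' summaries together with the reference genotype's own values. All artifacts
#' are seeded; re-running with the same inputs and seed reproduces every
#' output.
#'
#' @param universe the reaction universe.
#' @param currency currency metabolite ids.
#' @param reference the reference organism's genotype (metabolic reaction
#'   ids); used as chain start and comparison point.
#' @param levels ensemble levels to run, a prefix-closed subset of
#'   `c("R", "RM", "uRM", "uRM-V1", "uRM-V5", "uRM-V10")`.
#' @param media ordered list of [medium()] objects (glucose-analogue first);
#'   level `uRM-Vk` uses the first k.
#' @param params a [chain_params()] for the MCMC levels.
#' @param out_dir output directory (created); `NULL` keeps results in memory
#'   only.
#' @param seed integer seed for the whole run.
#' @param blocked precomputed blocked-reaction ids; computed via
#'   [find_blocked()] when needed and not supplied.
#' @param n_reactions genotype size; defaults to `length(reference)`.
#' @param max_metabolites metabolite cap; defaults to the reference's
#'   distinct-metabolite count.
#' @return list with `samples`, `stats` (per-level data.frames), `summary`
#'   (per-level mean/sd per statistic), `reference_stats`, `blocked`.
#' @export
run_pipeline <- function(universe, currency, reference, levels, media = list(),
                         params = chain_params(), out_dir = NULL, seed = 1L,
                         blocked = NULL, n_reactions = NULL,
                         max_metabolites = NULL) {
  set.seed(seed)
  known <- c("R", "RM", "uRM", "uRM-V1", "uRM-V5", "uRM-V10")
  bad <- setdiff(levels, known)
  if (length(bad)) stop("unknown level(s): ", paste(bad, collapse = ", "))
  if (is.null(n_reactions)) n_reactions <- length(reference)
  if (is.null(max_metabolites))
    max_metabolites <- distinct_metabolite_count(reference, universe)
  needs_unblocked <- any(levels %in% known[-(1:2)])
  if (needs_unblocked && is.null(blocked)) {
    message("[blocked] computing blocked reactions")
    blocked <- find_blocked(universe)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  reference_stats <- genotype_stats(reference, universe, currency)
  samples <- list(); stats <- list()
  for (lev in levels) {
    message("[", lev, "] sampling")
    spec <- ensemble_spec(lev, universe, n_reactions,
                          max_metabolites = max_metabolites,
                          blocked = blocked, environments = media)
    if (lev == "R") {
      genotypes <- sample_R(universe, n_reactions, params$n_save)
      samp <- structure(list(spec = spec, genotypes = genotypes,
                             acceptance_rate = 1, start = NULL, seed = seed),
                        class = "ensemble_sample")
    } else {
      samp <- run_mcmc(spec, universe, reference, params)
    }
    samples[[lev]] <- samp
    message("[", lev, "] statistics for ", length(samp$genotypes), " genotypes")
    stats[[lev]] <- ensemble_stats(samp, universe, currency)
    if (!is.null(out_dir)) {
      write_sample_jsonl(samp, file.path(out_dir, paste0(lev, "_genotypes.jsonl")))
      write.table(stats[[lev]], file.path(out_dir, paste0(lev, "_stats.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  summary <- .summarize_levels(stats, reference_stats)
  if (!is.null(out_dir)) {
    con <- file(file.path(out_dir, "summary.tsv"), "w")
    writeLines("# ensemble summaries: mean and population SD (n denominator) per statistic", con)
    write.table(summary, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    write.table(reference_stats, file.path(out_dir, "reference_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(samples = samples, stats = stats, summary = summary,
       reference_stats = reference_stats, blocked = blocked)
}

.summarize_levels <- function(stats, reference_stats) {
  rows <- list()
  for (lev in names(stats)) {
    df <- stats[[lev]]
    for (col in STAT_COLS) {
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev, statistic = col,
        mean = mean(df[[col]], na.rm = TRUE),
        sd = .pop_sd(df[[col]]),
        reference = reference_stats[[col]])
    }
  }
  do.call(rbind, rows)
}

#' Compare ensemble statistics to a reference genotype
#'
#' Per statistic and level: ensemble mean, population SD, reference value and
#' the z-score of the reference within the ensemble (`NA` when the SD is
#' zero). Also returns the cloud table of per-genotype `(P_C, gamma,
#' f_bowtie)` triplets used for the constraint-trend scatter view.
#'
#' @param stats named list of per-level statistics tables (from
#'   [ensemble_stats()] / [run_pipeline()]).
#' @param reference_stats one-row data.frame from [genotype_stats()].
#' @return list with `comparison` and `cloud` data.frames.
#' @export
compare_reference <- function(stats, reference_stats) {
  comparison <- .summarize_levels(stats, reference_stats)
  comparison$z <- ifelse(is.na(comparison$sd) | comparison$sd == 0,
                         NA_real_,
                         (comparison$reference - comparison$mean) / comparison$sd)
  cloud <- do.call(rbind, lapply(names(stats), function(lev)
    cbind(data.frame(level = lev), stats[[lev]][, c("P_C", "gamma", "f_bowtie")])))
  list(comparison = comparison, cloud = cloud)
}

#' Write or read an ensemble sample as JSON lines
#'
#' Line 1 is a metadata header (level, constraints, seed, acceptance rate);
#' each following line is one genotype as a sorted array of reaction ids.
#'
#' @param sample an `ensemble_sample`.
#' @param path output file.
#' @export
write_sample_jsonl <- function(sample, path) {
  meta <- list(level = sample$spec$level,
               n_reactions = sample$spec$n_reactions,
               max_metabolites = sample$spec$max_metabolites,
               n_environments = sample$spec$k,
               seed = sample$seed,
               acceptance_rate = sample$acceptance_rate)
  con <- file(path, "w")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"), con)
  for (g in sample$genotypes)
    writeLines(jsonlite::toJSON(sort(g)), con)
  close(con)
  invisible(path)
}

#' @rdname write_sample_jsonl
#' @return `read_sample_jsonl()` returns a list with `meta` and `genotypes`.
#' @export
read_sample_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- jsonlite::fromJSON(lines[1L])
  genotypes <- lapply(lines[-1L], function(l) as.character(jsonlite::fromJSON(l)))
  list(meta = meta, genotypes = genotypes)
}

#' Run the pipeline from a YAML or JSON configuration file
#'
#' Keys: `reactions` (reaction table path), `currency`, `reference_genotype`,
#' `levels`, `media` (list of medium files or inline specs), `out_dir`,
#' `seed`, and optional `chain` (burn_in/thin/n_save) and `n_reactions` /
#' `max_metabolites` overrides.
#'
#' @param path configuration file.
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  loaded <- load_universe(cfg$reactions, cfg$currency)
  reference <- read_genotype(cfg$reference_genotype, loaded$universe)
  media <- lapply(cfg$media, function(m) {
    if (is.character(m) && length(m) == 1L) read_medium(m)
    else medium(m$carbon_source, unlist(m$inorganics),
                m$carbon_uptake %||% 10, m$inorganic_uptake %||% 1000)
  })
  ch <- cfg$chain %||% list()
  params <- chain_params(burn_in = ch$burn_in %||% 1e5,
                         thin = ch$thin %||% 1e3,
                         n_save = ch$n_save %||% 1e3,
                         seed = cfg$seed %||% 1L)
  invisible(run_pipeline(loaded$universe, loaded$currency, reference,
                         levels = cfg$levels, media = media, params = params,
                         out_dir = cfg$out_dir, seed = cfg$seed %||% 1L,
                         n_reactions = cfg$n_reactions,
                         max_metabolites = cfg$max_metabolites))
}
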