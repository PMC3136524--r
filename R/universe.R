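#' @useDynLib metnull, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
#' @importFrom stats optimize runif setNames sd
#' @importFrom utils read.delim write.table head
"_PACKAGE"

# ---------------------------------------------------------------------------
# Reaction equation parsing
# ---------------------------------------------------------------------------

#' Parse a reaction equation string
#'
#' Equations use the interchange convention `<coef? met> (+ <coef? met>)*
#' (-> | <=>) <coef? met> (+ <coef? met>)*`. An omitted coefficient means 1;
#' coefficients may be decimals or fractions such as `1/2`. Metabolites on the
#' left receive negative stoichiometric coefficients, those on the right
#' positive ones; `<=>` marks the reaction reversible. A metabolite occurring
#' on both sides nets its coefficients and a zero net is an error; duplicate
#' mentions on one side sum.
#'
#' @param text equation string.
#' @param allow_empty_side allow one empty side, as in exchange (`"glc_e ->"`)
#'   or biomass sink reactions. Metabolic reactions must have both sides.
#' @return list with `stoich` (named numeric vector, negative = reactant) and
#'   `reversible` (logical).
#' @examples
#' parse_reaction_equation("glc-D + atp -> g6p + adp + h")
#' parse_reaction_equation("2 A + B <=> C")
#' @export
parse_reaction_equation <- function(text, allow_empty_side = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  reversible <- grepl("<=>", text, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "->"
  parts <- strsplit(text, arrow, fixed = TRUE)[[1L]]
  n_arrows <- lengths(regmatches(text, gregexpr(if (reversible) "<=>" else "->", text)))
  if (n_arrows != 1L)
    stop("equation must contain exactly one '->' or '<=>': ", sQuote(text))
  if (length(parts) == 1L) parts <- c(parts, "")
  lhs <- .parse_side(parts[1L], text)
  rhs <- .parse_side(parts[2L], text)
  if (length(lhs) == 0L && length(rhs) == 0L)
    stop("both sides empty in equation ", sQuote(text))
  if ((length(lhs) == 0L || length(rhs) == 0L) && !allow_empty_side)
    stop("empty side in equation ", sQuote(text))
  stoich <- c(-lhs, rhs)
  if (anyDuplicated(names(stoich))) {
    stoich <- tapply(stoich, factor(names(stoich), levels = unique(names(stoich))), sum)
    stoich <- setNames(as.numeric(stoich), names(stoich))
  }
  zero <- abs(stoich) < 1e-12
  if (any(zero))
    stop("metabolite ", sQuote(names(stoich)[zero][1L]),
         " nets to zero in equation ", sQuote(text))
  list(stoich = stoich, reversible = reversible)
}

.parse_side <- function(side, text) {
  side <- trimws(side)
  if (!nzchar(side)) return(setNames(numeric(0), character(0)))
  if (startsWith(side, "+") || endsWith(side, "+"))
    stop("malformed term (dangling '+') in equation ", sQuote(text))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
  if (any(!nzchar(terms)))
    stop("malformed term (empty between '+') in equation ", sQuote(text))
  coef <- numeric(length(terms))
  met <- character(length(terms))
  num_re <- "^([0-9]+\\.?[0-9]*|\\.[0-9]+|[0-9]+/[0-9]+)$"
  for (i in seq_along(terms)) {
    toks <- strsplit(terms[i], "[[:space:]]+")[[1L]]
    if (length(toks) == 1L) {
      if (grepl(num_re, toks))
        stop("malformed token ", sQuote(toks), " (bare number) in equation ", sQuote(text))
      coef[i] <- 1; met[i] <- toks
    } else if (length(toks) == 2L && grepl(num_re, toks[1L])) {
      coef[i] <- .parse_coef(toks[1L]); met[i] <- toks[2L]
    } else {
      stop("malformed token ", sQuote(terms[i]), " in equation ", sQuote(text))
    }
    if (coef[i] == 0)
      stop("zero coefficient for ", sQuote(met[i]), " in equation ", sQuote(text))
  }
  out <- setNames(coef, met)
  out
}

.parse_coef <- function(tok) {
  if (grepl("/", tok, fixed = TRUE)) {
    ab <- as.numeric(strsplit(tok, "/", fixed = TRUE)[[1L]])
    ab[1L] / ab[2L]
  } else as.numeric(tok)
}

#' Render a stoichiometry map back to an equation string
#'
#' Inverse of [parse_reaction_equation()]: parsing the rendered string
#' reproduces the stoichiometry exactly (coefficients are written with full
#' precision decimals).
#'
#' @param stoich named numeric vector, negative entries are reactants.
#' @param reversible logical, writes `<=>` instead of `->`.
#' @return equation string.
#' @export
format_reaction_equation <- function(stoich, reversible = FALSE) {
  fmt <- function(v) {
    vapply(seq_along(v), function(i) {
      cf <- abs(v[i])
      if (isTRUE(all.equal(cf, 1))) names(v)[i]
      else paste(format(cf, digits = 15, scientific = FALSE, trim = TRUE), names(v)[i])
    }, character(1))
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(paste(fmt(lhs), collapse = " + "),
        if (reversible) "<=>" else "->",
        paste(fmt(rhs), collapse = " + ")) |> trimws()
}

# ---------------------------------------------------------------------------
# Universe construction and IO
# ---------------------------------------------------------------------------

REACTION_CATEGORIES <- c("metabolic", "transport", "exchange", "biomass")

#' Assemble a reaction universe from parsed components
#'
#' Low-level constructor used by [load_universe()] and the synthetic
#' generator. Validates per-reaction invariants (exchange reactions touch
#' exactly one metabolite, metabolic reactions have at least one reactant and
#' one product, at most one biomass reaction) and builds the sparse
#' stoichiometric matrix.
#'
#' @param id character vector of unique reaction ids.
#' @param stoich list of named numeric stoichiometry vectors, one per reaction.
#' @param reversible logical vector.
#' @param category character vector over
#'   `c("metabolic", "transport", "exchange", "biomass")`.
#' @return object of class `metabolic_universe` with elements `reactions`
#'   (data.frame id/reversible/category), `stoich`, `metabolites` (data.frame
#'   id/external), `S` (sparse metabolite-by-reaction matrix), `N` (number of
#'   swappable metabolic reactions) and `biomass_id`.
#' @export
make_universe <- function(id, stoich, reversible, category) {
  stopifnot(length(id) == length(stoich),
            length(id) == length(reversible),
            length(id) == length(category))
  if (length(id) == 0L) stop("no reactions")
  if (anyDuplicated(id))
    stop("duplicate reaction id: ", sQuote(id[duplicated(id)][1L]))
  bad_cat <- setdiff(unique(category), REACTION_CATEGORIES)
  if (length(bad_cat))
    stop("unknown reaction category: ", sQuote(bad_cat[1L]))
  if (sum(category == "biomass") > 1L)
    stop("more than one biomass reaction")
  for (i in seq_along(id)) {
    st <- stoich[[i]]
    if (any(abs(st) < 1e-12)) stop("zero coefficient in reaction ", sQuote(id[i]))
    if (any(!nzchar(names(st))) || any(grepl("[[:space:]]", names(st))))
      stop("invalid metabolite id in reaction ", sQuote(id[i]))
    if (category[i] == "exchange" && length(st) != 1L)
      stop("exchange reaction ", sQuote(id[i]), " must touch exactly one metabolite")
    if (category[i] == "metabolic" && (!any(st < 0) || !any(st > 0)))
      stop("metabolic reaction ", sQuote(id[i]), " needs >=1 reactant and >=1 product")
  }
  met_ids <- unique(unlist(lapply(stoich, names), use.names = FALSE))
  ex_mets <- unlist(lapply(stoich[category == "exchange"], names), use.names = FALSE)
  metabolites <- data.frame(id = met_ids,
                            external = met_ids %in% ex_mets,
                            stringsAsFactors = FALSE)
  ii <- rep(seq_along(id), lengths(stoich))
  jj <- match(unlist(lapply(stoich, names), use.names = FALSE), met_ids)
  S <- Matrix::sparseMatrix(i = jj, j = ii,
                            x = unlist(stoich, use.names = FALSE),
                            dims = c(length(met_ids), length(id)),
                            dimnames = list(met_ids, id))
  names(stoich) <- id
  structure(list(
    reactions = data.frame(id = id, reversible = as.logical(reversible),
                           category = category, stringsAsFactors = FALSE),
    stoich = stoich,
    metabolites = metabolites,
    S = S,
    N = sum(category == "metabolic"),
    biomass_id = if (any(category == "biomass")) id[category == "biomass"] else NA_character_
  ), class = "metabolic_universe")
}

#' @export
print.metabolic_universe <- function(x, ...) {
  cat("<metabolic_universe>\n")
  cat("  reactions:  ", nrow(x$reactions),
      " (", x$N, " metabolic, ",
      sum(x$reactions$category == "transport"), " transport, ",
      sum(x$reactions$category == "exchange"), " exchange, ",
      sum(x$reactions$category == "biomass"), " biomass)\n", sep = "")
  cat("  metabolites:", nrow(x$metabolites),
      sprintf("(%d external)", sum(x$metabolites$external)), "\n")
  cat("  reversible: ", sum(x$reactions$reversible), "\n")
  invisible(x)
}

#' Reaction ids by category
#'
#' `metabolic_ids()` returns the swappable reactions; `scaffold_ids()` the
#' fixed transport/exchange/biomass backbone carried by every genotype.
#'
#' @param universe a `metabolic_universe`.
#' @return character vector of reaction ids.
#' @export
metabolic_ids <- function(universe) {
  universe$reactions$id[universe$reactions$category == "metabolic"]
}

#' @rdname metabolic_ids
#' @export
scaffold_ids <- function(universe) {
  universe$reactions$id[universe$reactions$category != "metabolic"]
}

#' Load a reaction universe (and optionally a currency list) from disk
#'
#' The reaction table is UTF-8 TSV with a header row and columns
#' `id`, `equation`, `reversible` (0/1, must agree with the `->`/`<=>` marker)
#' and `category`; lines starting `#` are comments. Counts by category and
#' reversibility are reported via `message()`.
#'
#' @param reaction_path path to the reaction table.
#' @param currency_path optional path to a currency-metabolite list (one id
#'   per line); ids not present in the universe are dropped with a warning.
#' @param quiet suppress the count messages.
#' @return list with elements `universe` and `currency` (NULL when no
#'   currency path was given).
#' @export
load_universe <- function(reaction_path, currency_path = NULL, quiet = FALSE) {
  tab <- read.delim(reaction_path, comment.char = "#", quote = "",
                    stringsAsFactors = FALSE)
  need <- c("id", "equation", "reversible", "category")
  if (!all(need %in% names(tab)))
    stop("reaction table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("no reactions in ", sQuote(reaction_path))
  parsed <- lapply(seq_len(nrow(tab)), function(i) {
    p <- parse_reaction_equation(tab$equation[i],
                                 allow_empty_side = tab$category[i] != "metabolic")
    flag <- as.logical(as.integer(tab$reversible[i]))
    if (!identical(p$reversible, flag))
      stop("reversibility flag disagrees with equation marker for reaction ",
           sQuote(tab$id[i]))
    p
  })
  uni <- make_universe(id = tab$id,
                       stoich = lapply(parsed, `[[`, "stoich"),
                       reversible = vapply(parsed, `[[`, logical(1), "reversible"),
                       category = tab$category)
  if (!quiet) {
    cts <- table(factor(uni$reactions$category, levels = REACTION_CATEGORIES))
    message(sprintf(
      "loaded %d reactions (%s), %d reversible / %d irreversible, %d metabolites",
      nrow(uni$reactions),
      paste(sprintf("%s=%d", names(cts), as.integer(cts)), collapse = ", "),
      sum(uni$reactions$reversible), sum(!uni$reactions$reversible),
      nrow(uni$metabolites)))
  }
  currency <- if (!is.null(currency_path)) read_currency(currency_path, uni) else NULL
  list(universe = uni, currency = currency)
}

#' Write a reaction universe as a TSV reaction table
#'
#' Round-trips through [load_universe()]: every reaction's stoichiometry and
#' reversibility is reproduced exactly.
#'
#' @param universe a `metabolic_universe`.
#' @param path output file.
#' @export
write_universe <- function(universe, path) {
  tab <- data.frame(
    id = universe$reactions$id,
    equation = vapply(seq_len(nrow(universe$reactions)), function(i)
      format_reaction_equation(universe$stoich[[i]], universe$reactions$reversible[i]),
      character(1)),
    reversible = as.integer(universe$reactions$reversible),
    category = universe$reactions$category,
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a currency-metabolite list
#'
#' Plain text, one metabolite id per line; `#` comments and blank lines are
#' ignored. When a universe is supplied, unresolvable ids are reported and
#' dropped with a warning (currency lists are shared across universes).
#'
#' @param path file path.
#' @param universe optional `metabolic_universe` used to resolve ids.
#' @return character vector of currency metabolite ids.
#' @export
read_currency <- function(path, universe = NULL) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (anyDuplicated(ids)) stop("duplicate id in currency list: ",
                               sQuote(ids[duplicated(ids)][1L]))
  if (!is.null(universe)) {
    missing <- setdiff(ids, universe$metabolites$id)
    if (length(missing)) {
      warning("dropping ", length(missing),
              " currency id(s) not in universe: ",
              paste(head(missing, 5L), collapse = ", "))
      ids <- setdiff(ids, missing)
    }
  }
  ids
}

#' @rdname read_currency
#' @param ids character vector of currency ids to write.
#' @export
write_currency <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read or write a genotype (one reaction id per line)
#'
#' @param path file path.
#' @param universe optional universe; membership in its metabolic reactions is
#'   then checked.
#' @return character vector of reaction ids.
#' @export
read_genotype <- function(path, universe = NULL) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (anyDuplicated(ids)) stop("duplicate reaction in genotype file")
  if (!is.null(universe)) .check_genotype(ids, universe)
  ids
}

#' @rdname read_genotype
#' @param genotype character vector of reaction ids.
#' @export
write_genotype <- function(genotype, path) {
  writeLines(genotype, path)
  invisible(path)
}

.check_genotype <- function(genotype, universe) {
  unknown <- setdiff(genotype, metabolic_ids(universe))
  if (length(unknown))
    stop("genotype contains non-metabolic or unknown reaction id(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Environments (minimal media)
# ---------------------------------------------------------------------------

#' Define a minimal chemical environment
#'
#' A minimal medium is a single limiting carbon source plus a set of inorganic
#' metabolites available in effectively unlimited amounts. Uptake is allowed
#' only for medium members (the carbon source at `carbon_uptake`, inorganics
#' at `inorganic_uptake`); secretion is allowed for every external metabolite.
#'
#' @param carbon_source external metabolite id of the carbon source.
#' @param inorganics character vector of external metabolite ids.
#' @param carbon_uptake maximum carbon uptake flux (default 10).
#' @param inorganic_uptake maximum inorganic uptake flux (default 1000).
#' @return object of class `medium`.
#' @export
medium <- function(carbon_source, inorganics = character(),
                   carbon_uptake = 10, inorganic_uptake = 1000) {
  stopifnot(is.character(carbon_source), length(carbon_source) == 1L,
            carbon_uptake > 0, inorganic_uptake > 0)
  structure(list(carbon_source = carbon_source,
                 inorganics = unique(as.character(inorganics)),
                 carbon_uptake = carbon_uptake,
                 inorganic_uptake = inorganic_uptake),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat("<medium> carbon:", x$carbon_source,
      sprintf("(uptake %.3g);", x$carbon_uptake),
      length(x$inorganics), "inorganics",
      sprintf("(uptake %.3g)\n", x$inorganic_uptake))
  invisible(x)
}

#' Read a minimal-medium definition from YAML or JSON
#'
#' Keys: `carbon_source`, `inorganics`, and optionally `carbon_uptake` and
#' `inorganic_uptake` (or a `bounds` list with those two entries).
#'
#' @param path file path; format chosen by `.json` extension, else YAML.
#' @return a [medium()] object.
#' @export
read_medium <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  b <- obj$bounds
  medium(carbon_source = obj$carbon_source,
         inorganics = unlist(obj$inorganics),
         carbon_uptake = obj$carbon_uptake %||% b$carbon_uptake %||% 10,
         inorganic_uptake = obj$inorganic_uptake %||% b$inorganic_uptake %||% 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Genotype-level summaries
# ---------------------------------------------------------------------------

#' Count the distinct metabolites of a genotype
#'
#' The number of metabolites m of a genotype is the number of distinct
#' metabolites associated with its (metabolic) reactions; the fixed
#' transport/exchange/biomass scaffold is excluded.
#'
#' @param genotype character vector of metabolic reaction ids.
#' @param universe a `metabolic_universe`.
#' @return non-negative integer.
#' @export
distinct_metabolite_count <- function(genotype, universe) {
  if (length(genotype) == 0L) return(0L)
  .check_genotype(genotype, universe)
  length(unique(unlist(lapply(universe$stoich[genotype], names), use.names = FALSE)))
}

#' Genotype dissimilarity
#'
#' Fraction of the reactions of `g2` that are not in `g1`:
#' `|g2 \ g1| / |g2|`. Asymmetric; 0 for identical genotypes, 1 for disjoint
#' ones.
#'
#' @param g1,g2 character vectors of reaction ids; `g2` must be nonempty.
#' @return fraction in `[0, 1]`.
#' @export
dissimilarity <- function(g1, g2) {
  if (length(g2) == 0L) stop("g2 is empty")
  length(setdiff(g2, g1)) / length(g2)
}
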