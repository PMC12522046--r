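# Bundled reaction sources. The generation pipeline only needs valid reaction
# SMILES as input; the bundled source provides (a) a small curated list of
# classic transformations and (b) a combinatorial generator that applies
# functional-group transforms to random scaffolds. The combinatorial graph is
# what makes multi-step patterns possible: chains for multiple-line schemes,
# stars for branches, and closed transform walks for catalytic-cycle layouts.

# scaffold + "C" + suffix is always a valid SMILES
.toy_scaffolds <- c("C", "CC", "CCC", "CCCC", "CC(C)", "CCCCC", "CCOC",
                    "C1CCCCC1", "c1ccccc1", "Cc1ccccc1", "CC(C)C", "CCCCCC")

.toy_fg <- c(alcohol = "O", aldehyde = "=O", acid = "(=O)O",
             ester = "(=O)OC", bromide = "Br", amine = "N",
             nitrile = "#N", acetate = "OC(C)=O")

# directed transform graph; co_reactant (SMILES) joins the reactant field,
# agents are reagent names rendered as condition text above the arrow
.toy_edges <- list(
  list(from = "alcohol", to = "aldehyde", agents = "DMP"),
  list(from = "alcohol", to = "bromide", agents = "PBr3"),
  list(from = "alcohol", to = "acetate", co_reactant = "CC(=O)Cl",
       agents = "Et3N"),
  list(from = "aldehyde", to = "acid", agents = "KMnO4"),
  list(from = "aldehyde", to = "alcohol", agents = "NaBH4"),
  list(from = "acid", to = "ester", co_reactant = "CO", agents = "TsOH"),
  list(from = "acid", to = "alcohol", agents = "LiAlH4"),
  list(from = "ester", to = "alcohol", agents = "LiAlH4"),
  list(from = "bromide", to = "amine", co_reactant = "N", agents = NULL),
  list(from = "bromide", to = "nitrile", co_reactant = "C#N",
       agents = "NaCN"))

# closed walks in the transform graph, usable for cycle layouts
.toy_cycles <- list(c("alcohol", "aldehyde", "acid"),
                    c("alcohol", "aldehyde", "acid", "ester"))

.toy_mol <- function(scaffold, fg) paste0(scaffold, "C", .toy_fg[[fg]])

.toy_edge <- function(from, to) {
  for (e in .toy_edges)
    if (identical(e$from, from) && identical(e$to, to)) return(e)
  NULL
}

.toy_step <- function(scaffold, from, to) {
  e <- .toy_edge(from, to)
  reactants <- c(.toy_mol(scaffold, from), e$co_reactant)
  list(reactants = reactants, agents = character(0),
       products = .toy_mol(scaffold, to),
       agent_names = e$agents %||% character(0))
}

#' Bundled toy reaction source
#'
#' A reaction source backed by a curated reaction list plus a combinatorial
#' functional-group-transform generator; supports all four layout patterns.
#'
#' @return An object of class `rxn_toy_source`.
#' @seealso [reaction_source_file()], [sample_steps()]
#' @export
toy_reaction_source <- function() {
  structure(list(), class = c("rxn_toy_source", "rxn_reaction_source"))
}

#' Reaction source from a file of reaction SMILES
#'
#' One reaction SMILES per line (`reactants>agents>products`). A plain list
#' carries no transform structure, so this source supports the single-line,
#' multiple-line and branch patterns (branch arms reuse one reaction under
#' independently sampled conditions) but not cycles.
#'
#' @param path File path, or a character vector of reaction SMILES.
#' @return An object of class `rxn_file_source`.
#' @export
reaction_source_file <- function(path) {
  rxns <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else as.character(path)
  rxns <- trimws(rxns)
  rxns <- rxns[nzchar(rxns)]
  if (!length(rxns)) stop("reaction source is empty")
  structure(list(reactions = rxns),
            class = c("rxn_file_source", "rxn_reaction_source"))
}

#' Curated toy reactions
#'
#' A small list of classic single-step reaction SMILES, usable as a file-style
#' reaction source in examples and tests.
#'
#' @return Character vector of reaction SMILES.
#' @export
toy_reactions <- function() {
  c("CCO>>CC=O",
    "CC=O>>CC(=O)O",
    "CC(=O)O.CO>[H+]>CC(=O)OC",
    "CCO.CC(=O)O>>CC(=O)OCC",
    "c1ccccc1C=O>>c1ccccc1CO",
    "CCBr.[N-]=[N+]=[N-]>>CCN=[N+]=[N-]",
    "CCCO>>CCC=O",
    "CCC=O>>CCC(=O)O",
    "C1CCCCC1CO>>C1CCCCC1C=O",
    "Cc1ccccc1CBr.C#N>>Cc1ccccc1CC#N",
    "CC(C)CO>>CC(C)CBr",
    "CCCCBr.N>>CCCCN",
    "c1ccccc1CCO>>c1ccccc1CC=O",
    "CC(=O)Cl.CCO>>CC(=O)OCC",
    "CCCC=O>>CCCCO",
    "CC(C)C(=O)O.CO>>CC(C)C(=O)OC")
}

#' Which layout patterns can a source provide?
#'
#' @param source A reaction source.
#' @return Character vector of supported pattern names.
#' @export
supported_patterns <- function(source) UseMethod("supported_patterns")

#' @export
supported_patterns.rxn_toy_source <- function(source) SCHEME_PATTERNS

#' @export
supported_patterns.rxn_file_source <- function(source)
  setdiff(SCHEME_PATTERNS, "cycle")

#' Sample abstract reaction steps for one scheme
#'
#' Returns `k` abstract steps compatible with `pattern`: chained steps for
#' multiple-line schemes when the source allows it, a common first reactant
#' for branches, and a closed reactant/product walk for cycles. Each step is
#' a list with `reactants`, `agents` (SMILES agents), `products`,
#' `agent_names` (reagent names for condition text) and `source_smiles` (the
#' reaction SMILES the step was generated from).
#'
#' @param source A reaction source.
#' @param pattern Layout pattern name.
#' @param k Number of steps (arms for branch, >= 3 for cycle).
#' @param rng An [rng_stream()].
#' @return List of `k` abstract steps.
#' @export
sample_steps <- function(source, pattern, k, rng) UseMethod("sample_steps")

.finish_step <- function(st) {
  st$source_smiles <- paste0(paste(st$reactants, collapse = "."), ">",
                             paste(st$agents, collapse = "."), ">",
                             paste(st$products, collapse = "."))
  st
}

#' @export
sample_steps.rxn_toy_source <- function(source, pattern, k, rng) {
  pattern <- match.arg(pattern, SCHEME_PATTERNS)
  with_rng(rng, {
    scaffold <- sample(.toy_scaffolds, 1)
    steps <- switch(
      pattern,
      single_line = {
        e <- .toy_edges[[sample(length(.toy_edges), 1)]]
        list(.toy_step(scaffold, e$from, e$to))
      },
      multiple_line = {
        # random walk of length k in the transform graph; a dead end restarts
        # the walk, breaking the chain for that row
        node <- "alcohol"
        out <- list()
        for (i in seq_len(k)) {
          nexts <- Filter(function(e) identical(e$from, node), .toy_edges)
          chained <- i > 1
          if (!length(nexts)) {
            node <- "alcohol"
            chained <- FALSE
            nexts <- Filter(function(e) identical(e$from, node), .toy_edges)
          }
          e <- nexts[[sample(length(nexts), 1)]]
          st <- .toy_step(scaffold, e$from, e$to)
          if (chained) st$reuse_reactant_of <- i - 1
          out[[i]] <- st
          node <- e$to
        }
        out
      },
      branch = {
        outs <- Filter(function(e) identical(e$from, "alcohol"), .toy_edges)
        pick <- sample(length(outs), min(k, length(outs)))
        lapply(outs[pick], function(e) {
          st <- .toy_step(scaffold, e$from, e$to)
          st$shared_reactant <- TRUE
          st
        })
      },
      cycle = {
        walks <- Filter(function(w) length(w) == k, .toy_cycles)
        if (!length(walks))
          stop("no closed transform walk of length ", k,
               "; cycle supports k in {3, 4}")
        w <- walks[[sample(length(walks), 1)]]
        lapply(seq_along(w), function(i) {
          st <- .toy_step(scaffold, w[i], w[(i %% length(w)) + 1])
          st$reactants <- st$reactants[1]  # cycle nodes are single molecules
          st
        })
      })
    lapply(steps, .finish_step)
  })
}

#' @export
sample_steps.rxn_file_source <- function(source, pattern, k, rng) {
  pattern <- match.arg(pattern, SCHEME_PATTERNS)
  if (identical(pattern, "cycle"))
    stop("a plain reaction list cannot chain into a cycle; ",
         "use the toy source or a file with chainable reactions")
  with_rng(rng, {
    from_rxn <- function(rxn) {
      p <- parse_reaction_smiles(rxn)
      if (!length(p$reactants) || !length(p$products))
        stop("reaction needs >= 1 reactant and product: ", rxn)
      list(reactants = p$reactants, agents = p$agents, products = p$products,
           agent_names = character(0))
    }
    steps <- switch(
      pattern,
      single_line = list(from_rxn(sample(source$reactions, 1))),
      multiple_line = lapply(sample(source$reactions, k, replace = TRUE),
                             from_rxn),
      branch = {
        rxn <- sample(source$reactions, 1)
        lapply(seq_len(k), function(i) {
          st <- from_rxn(rxn)
          st$shared_reactant <- TRUE
          st
        })
      })
    lapply(steps, .finish_step)
  })
}
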