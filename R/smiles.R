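# SMILES layer: canonicalization, validity, reaction-SMILES grammar and
# equality. Canonicalization is pluggable; the default backend is Open Babel
# via ChemmineOB. Results are memoized per session (schemes reuse a small
# molecule set heavily).

.rxn_cache <- new.env(parent = emptyenv())

.cache_get <- function(key) {
  if (exists(key, envir = .rxn_cache, inherits = FALSE))
    get(key, envir = .rxn_cache, inherits = FALSE) else NULL
}
.cache_set <- function(key, value) assign(key, value, envir = .rxn_cache)

.default_canonicalizer <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  out <- sub("[ \t\r\n]+$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

#' Set or get the molecule canonicalizer
#'
#' Equality of molecules and reactions is defined on the output strings of a
#' single canonicalizer: a function mapping one SMILES string to its canonical
#' form, or `NA_character_` if the input does not parse.
#'
#' @param fn A function `function(smiles) -> character(1)`, or `NULL` to reset
#'   to the Open Babel default.
#' @return The previously installed canonicalizer, invisibly.
#' @export
set_canonicalizer <- function(fn = NULL) {
  old <- .cache_get(".canonicalizer")
  if (is.null(fn)) fn <- .default_canonicalizer
  stopifnot(is.function(fn))
  .cache_set(".canonicalizer", fn)
  # canonical forms memoized under the old backend are stale
  stale <- grep("^can:", ls(envir = .rxn_cache), value = TRUE)
  if (length(stale)) rm(list = stale, envir = .rxn_cache)
  invisible(old)
}

.canonicalizer <- function() {
  fn <- .cache_get(".canonicalizer")
  if (is.null(fn)) {
    fn <- .default_canonicalizer
    .cache_set(".canonicalizer", fn)
  }
  fn
}

#' Canonical SMILES of one molecule
#'
#' @param smiles A single-molecule SMILES string.
#' @return The canonical form, or `NA_character_` if `smiles` does not parse.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  key <- paste0("can:", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  val <- .canonicalizer()(smiles)
  .cache_set(key, val)
  val
}

#' Does a string parse as a single-molecule SMILES?
#'
#' @param smiles Candidate string.
#' @return `TRUE` iff the canonicalizer accepts it.
#' @export
smiles_valid <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

#' Parse a reaction SMILES string
#'
#' Splits `reactants>agents>products` on the two `>` separators and each field
#' on `.` into molecule SMILES. Empty fields yield empty vectors.
#'
#' @param rxn Reaction SMILES string.
#' @return A list with character vectors `reactants`, `agents`, `products`.
#' @export
parse_reaction_smiles <- function(rxn) {
  stopifnot(is.character(rxn), length(rxn) == 1)
  parts <- strsplit(rxn, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2 && endsWith(rxn, ">")) parts <- c(parts, "")
  if (length(parts) != 3)
    stop("not a reaction SMILES (need exactly two '>' separators): ", rxn)
  field <- function(s) {
    if (!nzchar(s)) character(0)
    else strsplit(s, ".", fixed = TRUE)[[1]]
  }
  list(reactants = field(parts[1]), agents = field(parts[2]),
       products = field(parts[3]))
}

# Canonical, order-insensitive key for one reaction. Per-molecule canonical
# forms are sorted within each field so the key is invariant to molecule
# order; errors name the offending molecule.
.reaction_key <- function(rxn, include_agents = FALSE, label = "reaction") {
  p <- parse_reaction_smiles(rxn)
  canon_field <- function(mols) {
    out <- vapply(mols, canonical_smiles, character(1))
    if (anyNA(out)) {
      bad <- mols[is.na(out)]
      stop(label, ": SMILES does not parse: ", paste(bad, collapse = ", "))
    }
    paste(sort(out), collapse = ".")
  }
  fields <- c(canon_field(p$reactants),
              if (include_agents) canon_field(p$agents) else "",
              canon_field(p$products))
  paste(fields, collapse = ">")
}

#' Reaction SMILES equality
#'
#' Two reactions are equal iff the canonical-form molecule multisets of their
#' fields agree; molecule order within a field is irrelevant. Agents are
#' ignored by default (the strict variant compares them too).
#'
#' @param a,b Reaction SMILES strings.
#' @param include_agents Compare the agent field as well?
#' @return `TRUE` or `FALSE`.
#' @export
reaction_equal <- function(a, b, include_agents = FALSE) {
  ka <- .reaction_key(a, include_agents, label = "left reaction")
  kb <- .reaction_key(b, include_agents, label = "right reaction")
  identical(ka, kb)
}

# 2D geometry of a molecule from Open Babel gen2D coordinates: atom positions
# and element symbols, bond list with orders, coordinate-unit extent (bond
# length ~ 1). Memoized per SMILES.
mol_geometry <- function(smiles) {
  key <- paste0("geom:", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  if (!smiles_valid(smiles))
    stop("cannot depict, SMILES does not parse: ", smiles)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf)) stop("depiction backend failed for SMILES: ", smiles)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  sym <- sub("_\\d+$", "", rownames(ab))
  x <- ab[, 1]; y <- ab[, 2]
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  g <- list(
    x = as.numeric(x), y = as.numeric(y), symbol = sym, bonds = bonds,
    width = if (length(x)) diff(range(x)) else 0,
    height = if (length(y)) diff(range(y)) else 0)
  .cache_set(key, g)
  g
}
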