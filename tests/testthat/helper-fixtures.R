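# Fixtures are built in code: a hand-made single-step scheme for the model
# tests and a generator wrapper producing laid-out (not rendered) schemes.

# 1-step scheme on a 400x200 canvas: ethanol --[H2 over Pd/C in THF]--> acetaldehyde
make_simple_scheme <- function(agent_texts = c("H2", "Pd/C"),
                               arrow_kind = "straight",
                               crossed_out = FALSE) {
  items <- c(
    lapply(agent_texts, function(a)
      condition_item(a, "agent", bbox(170, 60, 230, 80))),
    list(condition_item("THF", "solvent", bbox(175, 110, 225, 130))))
  # give agent items distinct boxes so item pairing is unambiguous
  if (length(agent_texts) >= 1)
    items[[1]]$bbox <- bbox(150, 60, 195, 80)
  if (length(agent_texts) >= 2)
    items[[2]]$bbox <- bbox(205, 60, 250, 80)
  comps <- list(
    component("r1", "reactant", bbox(20, 70, 120, 130), smiles = "CCO"),
    component("cond", "condition", bbox(150, 60, 250, 130), items = items),
    component("p1", "product", bbox(280, 70, 380, 130), smiles = "CC=O"))
  step <- reaction_step("r1", "cond", "p1",
                        arrow(c(140, 100), c(270, 100), arrow_kind,
                              crossed_out = crossed_out))
  reaction_scheme(400, 200, comps, list(step), "single_line")
}

# laid-out scheme from the bundled source, deterministic in (seed, i)
gen_scheme <- function(i, seed = 20240601, pattern = NULL,
                       style = style_config(), spec = condition_spec()) {
  src <- toy_reaction_source()
  rng <- rng_fork(rng_stream(seed), i)
  pat <- pattern %||% with_rng(rng, sample(SCHEME_PATTERNS, 1))
  k <- with_rng(rng_fork(rng, 2),
                switch(pat, single_line = 1L, multiple_line = sample(2:3, 1),
                       branch = sample(2:3, 1), cycle = sample(3:4, 1)))
  steps <- sample_steps(src, pat, k, rng)
  steps <- lapply(seq_along(steps), function(j) {
    st <- steps[[j]]
    spec_j <- spec
    if (length(st$agents) || length(st$agent_names))
      spec_j$p_role_present[["agent"]] <- 0
    st$conditions <- c(lapply(st$agent_names %||% character(0),
                              function(a) condition_item(a, "agent")),
                       sample_conditions(rng_fork(rng, 10 + j), spec_j))
    st
  })
  layout_scheme(steps, pat, style, rng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

all_items <- function(scheme) {
  out <- list()
  for (cmp in scheme$components)
    if (identical(cmp$role, "condition")) out <- c(out, cmp$items)
  out
}

molecule_components <- function(scheme)
  Filter(function(cmp) !identical(cmp$role, "condition"), scheme$components)

# relabel every agent-bearing condition of a scheme as a predicted reactant
# (the soft-match relaxation case), leaving everything else untouched
agents_as_reactants <- function(scheme) {
  out <- scheme
  moved <- character(0)
  out$steps <- lapply(scheme$steps, function(st) {
    keep <- character(0)
    for (id in st$condition_ids) {
      cmp <- Filter(function(cm) identical(as.character(cm$id), id),
                    scheme$components)[[1]]
      has_agent <- any(vapply(cmp$items, function(it)
        identical(it$role, "agent"), logical(1)))
      if (has_agent) {
        st$reactant_ids <- c(st$reactant_ids, id)
        moved <<- c(moved, id)
      } else keep <- c(keep, id)
    }
    st$condition_ids <- keep
    st
  })
  out$components <- lapply(scheme$components, function(cmp) {
    if (as.character(cmp$id) %in% moved) {
      cmp$role <- "reactant"; cmp$smiles <- "*"; cmp$items <- NULL
    }
    cmp
  })
  out
}

# brute-force maximum number of matched pred/gt step pairs by enumerating
# all injections from the smaller side into the larger
brute_force_matching <- function(adj) {
  nl <- nrow(adj); nr <- ncol(adj)
  if (nl == 0 || nr == 0) return(0L)
  transpose <- nl > nr
  if (transpose) { adj <- t(adj); tmp <- nl; nl <- nr; nr <- tmp }
  best <- 0L
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i], k - 1))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  for (asgn in perms(seq_len(nr), nl))
    best <- max(best, sum(adj[cbind(seq_len(nl), asgn)]))
  best
}
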