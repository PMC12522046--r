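# Domain model for reaction schemes: axis-aligned boxes (pixels, origin
# top-left, half-open on the max edges), role-labelled components, condition
# items, arrows, reaction steps and the scheme container.

#' Axis-aligned bounding box
#'
#' Pixel coordinates with the origin at the top-left of the canvas; the box is
#' half-open, covering `[x_min, x_max) x [y_min, y_max)`.
#'
#' @param x_min,y_min,x_max,y_max Box edges in pixels; `x_min < x_max`,
#'   `y_min < y_max`, all non-negative.
#' @return An object of class `rxn_bbox`.
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  structure(list(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                 x_max = as.numeric(x_max), y_max = as.numeric(y_max)),
            class = "rxn_bbox")
}

bbox_valid <- function(b) {
  inherits(b, "rxn_bbox") &&
    all(vapply(b, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
               logical(1))) &&
    b$x_min < b$x_max && b$y_min < b$y_max && b$x_min >= 0 && b$y_min >= 0
}

bbox_center <- function(b) c((b$x_min + b$x_max) / 2, (b$y_min + b$y_max) / 2)
bbox_area <- function(b) (b$x_max - b$x_min) * (b$y_max - b$y_min)

#' Intersection-over-union of two boxes
#'
#' @param a,b `rxn_bbox` objects.
#' @return IoU in `[0, 1]`; 0 when the boxes do not overlap.
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- ix * iy
  if (inter <= 0) return(0)
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

bbox_contains <- function(outer, inner, tol = 1e-6) {
  inner$x_min >= outer$x_min - tol && inner$y_min >= outer$y_min - tol &&
    inner$x_max <= outer$x_max + tol && inner$y_max <= outer$y_max + tol
}

#' One condition text span
#'
#' @param text Rendered text (non-empty).
#' @param role One of `"agent"`, `"solvent"`, `"temperature"`, `"time"`,
#'   `"yield"`, `"other"`. Items with role `"other"` carry no role token when
#'   serialized to a token sequence.
#' @param bbox Sub-box inside the owning condition component, or `NULL` before
#'   layout.
#' @return An object of class `rxn_condition_item`.
#' @export
condition_item <- function(text, role, bbox = NULL) {
  role <- match.arg(role, CONDITION_ROLES)
  structure(list(text = text, role = role, bbox = bbox),
            class = "rxn_condition_item")
}

#' @rdname condition_item
#' @format `CONDITION_ROLES` is the ordered role vocabulary.
#' @export
CONDITION_ROLES <- c("agent", "solvent", "temperature", "time", "yield", "other")

#' A reaction-scheme component
#'
#' A localized region with a role. Molecule components (`reactant`, `product`)
#' carry a SMILES payload; `condition` components carry an ordered list of
#' [condition_item()]s.
#'
#' @param id Opaque identifier, unique within a scheme.
#' @param role `"reactant"`, `"condition"` or `"product"`.
#' @param bbox An [bbox()].
#' @param smiles Molecule payload (molecule components only).
#' @param items List of condition items (condition components only).
#' @return An object of class `rxn_component`.
#' @export
component <- function(id, role, bbox, smiles = NULL, items = NULL) {
  role <- match.arg(role, c("reactant", "condition", "product"))
  structure(list(id = id, role = role, bbox = bbox, smiles = smiles,
                 items = items),
            class = "rxn_component")
}

#' A reaction arrow
#'
#' @param start,end Numeric `c(x, y)` endpoints in pixels; must differ.
#' @param kind `"straight"`, `"curved"` or `"bidirectional"`.
#' @param crossed_out Is the arrow struck through with a cross (a reaction
#'   that does not occur)?
#' @param control For curved arrows, a list of >= 1 control points `c(x, y)`.
#' @return An object of class `rxn_arrow`.
#' @export
arrow <- function(start, end, kind = "straight", crossed_out = FALSE,
                  control = NULL) {
  kind <- match.arg(kind, c("straight", "curved", "bidirectional"))
  structure(list(start = as.numeric(start), end = as.numeric(end), kind = kind,
                 crossed_out = isTRUE(crossed_out), control = control),
            class = "rxn_arrow")
}

#' One reaction step
#'
#' @param reactant_ids,condition_ids,product_ids Component id vectors;
#'   at least one reactant and one product, conditions may be empty.
#' @param arrow An [arrow()].
#' @return An object of class `rxn_step`.
#' @export
reaction_step <- function(reactant_ids, condition_ids = character(0),
                          product_ids, arrow) {
  structure(list(reactant_ids = as.character(reactant_ids),
                 condition_ids = as.character(condition_ids),
                 product_ids = as.character(product_ids), arrow = arrow),
            class = "rxn_step")
}

#' A full reaction scheme
#'
#' The single source of truth for an image and its annotation: canvas size,
#' components, steps and the layout pattern.
#'
#' @param canvas_width,canvas_height Canvas extent in pixels.
#' @param components List of [component()]s with unique ids.
#' @param steps List of [reaction_step()]s.
#' @param pattern `"single_line"`, `"multiple_line"`, `"branch"` or `"cycle"`.
#' @param style_draw Optional concrete style draw (see [draw_style()]) kept
#'   for rendering.
#' @param decorations Internal layout extras (plus-sign positions, ...).
#' @return An object of class `rxn_scheme`.
#' @export
reaction_scheme <- function(canvas_width, canvas_height, components, steps,
                            pattern, style_draw = NULL, decorations = NULL) {
  pattern <- match.arg(pattern, SCHEME_PATTERNS)
  structure(list(canvas_width = as.numeric(canvas_width),
                 canvas_height = as.numeric(canvas_height),
                 components = components, steps = steps, pattern = pattern,
                 style_draw = style_draw, decorations = decorations),
            class = "rxn_scheme")
}

#' @rdname reaction_scheme
#' @format `SCHEME_PATTERNS` is the layout pattern vocabulary.
#' @export
SCHEME_PATTERNS <- c("single_line", "multiple_line", "branch", "cycle")

scheme_component <- function(scheme, id) {
  for (cmp in scheme$components) if (identical(cmp$id, id)) return(cmp)
  NULL
}

#' Validate a reaction scheme
#'
#' Checks every structural invariant of the domain model and returns the
#' violations as data, not exceptions: box ordering and canvas containment,
#' payload/role coherence, SMILES parseability, arrow geometry, id resolution
#' and uniqueness, step completeness, and that every component is referenced
#' by at least one step.
#'
#' @param scheme An [reaction_scheme()].
#' @return A data frame with columns `entity`, `rule`, `message`; zero rows
#'   iff the scheme is well formed.
#' @export
validate_scheme <- function(scheme) {
  v <- list()
  bad <- function(entity, rule, message)
    v[[length(v) + 1]] <<- data.frame(entity = entity, rule = rule,
                                      message = message)
  if (!inherits(scheme, "rxn_scheme")) {
    bad("scheme", "type", "not an rxn_scheme")
    return(do.call(rbind, v))
  }
  W <- scheme$canvas_width; H <- scheme$canvas_height
  if (!is.finite(W) || !is.finite(H) || W <= 0 || H <= 0)
    bad("scheme", "canvas", "canvas extent must be positive")

  ids <- vapply(scheme$components, function(cmp) as.character(cmp$id),
                character(1))
  if (anyDuplicated(ids))
    bad("scheme", "unique ids",
        paste("duplicated component id:",
              paste(unique(ids[duplicated(ids)]), collapse = ", ")))

  check_box <- function(b, entity, within = NULL) {
    if (!bbox_valid(b)) {
      bad(entity, "bbox order", "requires x_min < x_max, y_min < y_max, >= 0")
      return(invisible(FALSE))
    }
    if (is.finite(W) && is.finite(H) &&
        (b$x_max > W + 1e-6 || b$y_max > H + 1e-6))
      bad(entity, "bbox outside canvas",
          sprintf("box (%.1f,%.1f,%.1f,%.1f) exceeds canvas %gx%g",
                  b$x_min, b$y_min, b$x_max, b$y_max, W, H))
    if (!is.null(within) && !bbox_contains(within, b))
      bad(entity, "item box outside component",
          "condition item box must lie inside its component box")
    invisible(TRUE)
  }

  for (cmp in scheme$components) {
    ent <- paste0("component ", cmp$id)
    check_box(cmp$bbox, ent)
    if (identical(cmp$role, "condition")) {
      if (is.null(cmp$items) || !length(cmp$items))
        bad(ent, "payload", "condition component needs condition items")
      if (!is.null(cmp$smiles))
        bad(ent, "payload", "condition component cannot carry SMILES")
      for (it in cmp$items %||% list()) {
        if (!nzchar(it$text %||% ""))
          bad(ent, "item text", "condition item text must be non-empty")
        if (!is.null(it$bbox)) check_box(it$bbox, ent, within = cmp$bbox)
      }
    } else {
      if (is.null(cmp$smiles) || !is.character(cmp$smiles))
        bad(ent, "payload", "molecule component needs a SMILES payload")
      else if (!smiles_valid(cmp$smiles))
        bad(ent, "smiles", paste("SMILES does not parse:", cmp$smiles))
      if (!is.null(cmp$items))
        bad(ent, "payload", "molecule component cannot carry condition items")
    }
  }

  referenced <- character(0)
  for (k in seq_along(scheme$steps)) {
    st <- scheme$steps[[k]]
    ent <- paste0("step ", k)
    if (!length(st$reactant_ids)) bad(ent, "step missing reactant",
                                      "needs >= 1 reactant id")
    if (!length(st$product_ids)) bad(ent, "step missing product",
                                     "needs >= 1 product id")
    for (id in c(st$reactant_ids, st$condition_ids, st$product_ids)) {
      if (!id %in% ids)
        bad(ent, "unresolved id", paste("no component with id", id))
      referenced <- c(referenced, id)
    }
    for (id in st$condition_ids) {
      cmp <- scheme_component(scheme, id)
      if (!is.null(cmp) && !identical(cmp$role, "condition"))
        bad(ent, "role mismatch",
            paste("condition_ids must reference condition components:", id))
    }
    for (id in c(st$reactant_ids, st$product_ids)) {
      cmp <- scheme_component(scheme, id)
      if (!is.null(cmp) && identical(cmp$role, "condition"))
        bad(ent, "role mismatch",
            paste("molecule slot references a condition component:", id))
    }
    a <- st$arrow
    if (!inherits(a, "rxn_arrow")) {
      bad(ent, "arrow", "step needs an arrow")
    } else {
      if (isTRUE(all(a$start == a$end)))
        bad(ent, "arrow degenerate", "arrow start must differ from end")
      if (identical(a$kind, "curved") && (is.null(a$control) ||
                                          !length(a$control)))
        bad(ent, "arrow control", "curved arrow needs >= 1 control point")
    }
  }
  orphans <- setdiff(ids, referenced)
  for (id in orphans)
    bad(paste0("component ", id), "unreferenced component",
        "every component must be referenced by >= 1 step")
  if (!length(v))
    data.frame(entity = character(0), rule = character(0),
               message = character(0))
  else do.call(rbind, v)
}

#' Assemble the reaction SMILES of one step
#'
#' Reactant and product fields come from the molecule payloads in the step's
#' component order; the agent field collects those condition items, in item
#' order, whose text parses as SMILES (name-only agents such as `"Pd/C"` stay
#' in the condition annotation and do not enter the string).
#'
#' @param step An [reaction_step()] belonging to `scheme`.
#' @param scheme The owning [reaction_scheme()].
#' @return A reaction SMILES string `reactants>agents>products`.
#' @export
assemble_reaction_smiles <- function(step, scheme) {
  get_mol <- function(id) {
    cmp <- scheme_component(scheme, id)
    if (is.null(cmp)) stop("unresolved component id: ", id)
    if (is.null(cmp$smiles)) stop("component ", id, " has no SMILES payload")
    if (!smiles_valid(cmp$smiles))
      stop("SMILES payload does not parse: ", cmp$smiles)
    cmp$smiles
  }
  reactants <- vapply(step$reactant_ids, get_mol, character(1))
  products <- vapply(step$product_ids, get_mol, character(1))
  agents <- character(0)
  for (id in step$condition_ids) {
    cmp <- scheme_component(scheme, id)
    if (is.null(cmp)) stop("unresolved component id: ", id)
    for (it in cmp$items %||% list()) {
      if (identical(it$role, "agent") && smiles_valid(it$text))
        agents <- c(agents, it$text)
    }
  }
  paste0(paste(reactants, collapse = "."), ">",
         paste(agents, collapse = "."), ">",
         paste(products, collapse = "."))
}

#' Expand bidirectional arrows and drop crossed-out steps
#'
#' Reversible reactions drawn with a bidirectional arrow denote both
#' directions: each such step is replaced by two straight-arrow steps, the
#' second with reactants and products swapped. Steps whose arrow is crossed
#' out denote reactions that do not occur and are removed (components left
#' unreferenced by the removal are dropped too). Idempotent.
#'
#' @param scheme An [reaction_scheme()].
#' @return A new scheme with only straight/curved one-way steps.
#' @export
expand_bidirectional <- function(scheme) {
  out <- list()
  for (st in scheme$steps) {
    if (isTRUE(st$arrow$crossed_out)) next
    if (identical(st$arrow$kind, "bidirectional")) {
      fwd <- arrow(st$arrow$start, st$arrow$end, "straight")
      rev <- arrow(st$arrow$end, st$arrow$start, "straight")
      out[[length(out) + 1]] <- reaction_step(st$reactant_ids,
                                              st$condition_ids,
                                              st$product_ids, fwd)
      out[[length(out) + 1]] <- reaction_step(st$product_ids,
                                              st$condition_ids,
                                              st$reactant_ids, rev)
    } else {
      out[[length(out) + 1]] <- st
    }
  }
  kept <- unique(unlist(lapply(out, function(s)
    c(s$reactant_ids, s$condition_ids, s$product_ids))))
  comps <- Filter(function(cmp) as.character(cmp$id) %in% kept,
                  scheme$components)
  reaction_scheme(scheme$canvas_width, scheme$canvas_height, comps, out,
                  scheme$pattern, scheme$style_draw, scheme$decorations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
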