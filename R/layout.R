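# Layout: turn abstract reaction steps into a ReactionScheme with placed
# boxes (not yet rastered). Four patterns are supported. Shared conventions:
# agent text sits on the left of the arrow's travel direction (above, for a
# horizontal left-to-right arrow), all other condition roles on the right
# (below); molecule boxes never overlap by construction; content wider than
# canvas_max_width wraps onto a continuation line (line patterns only).

.PAD <- 24        # canvas padding, px
.GAP <- 16        # horizontal gap between elements, px
.COND_GAP <- 7    # gap between arrow line and condition text, px
.ROW_GAP <- 26    # vertical gap between lines/rows, px

est_text_w <- function(text, fs) ceiling(0.62 * fs * nchar(text) + 6)
est_text_h <- function(fs) ceiling(1.35 * fs)

.mol_size <- function(smiles, scale) {
  g <- mol_geometry(smiles)
  c(w = max(28, (g$width + 1.0) * scale), h = max(28, (g$height + 1.0) * scale))
}

# --- accumulator ------------------------------------------------------------

.new_env <- function() {
  e <- new.env(parent = emptyenv())
  e$components <- list(); e$steps <- list(); e$decorations <- list()
  e$n <- 0L
  e
}

.add_component <- function(env, role, box, smiles = NULL, items = NULL) {
  env$n <- env$n + 1L
  id <- sprintf("c%02d", env$n)
  env$components[[id]] <- component(id, role, box, smiles = smiles,
                                    items = items)
  id
}

.add_step <- function(env, r_ids, c_ids, p_ids, arr, source_smiles) {
  st <- reaction_step(r_ids, c_ids, p_ids, arr)
  st$source_smiles <- source_smiles
  env$steps[[length(env$steps) + 1]] <- st
}

.add_decoration <- function(env, type, x, y, size)
  env$decorations[[length(env$decorations) + 1]] <-
    list(type = type, x = x, y = y, size = size)

# --- condition block metrics ------------------------------------------------

# split items into the agent line (left of travel) and the stacked block of
# the remaining roles (right of travel), with estimated extents
.cond_blocks <- function(items, fs, rotation = 0) {
  th <- est_text_h(fs)
  measure <- function(it) {
    w <- est_text_w(it$text, fs); h <- th
    if (rotation != 0) {
      a <- abs(rotation) * pi / 180
      wh <- c(w * cos(a) + h * sin(a), w * sin(a) + h * cos(a))
      w <- wh[1]; h <- wh[2]
    }
    c(w = w, h = h)
  }
  is_agent <- vapply(items, function(it) identical(it$role, "agent"),
                     logical(1))
  above <- items[is_agent]
  below <- items[!is_agent]
  ord <- order(match(vapply(below, `[[`, "", "role"), CONDITION_ROLES))
  below <- below[ord]
  a_sz <- lapply(above, measure); b_sz <- lapply(below, measure)
  list(
    above = above, below = below, a_sz = a_sz, b_sz = b_sz,
    above_w = if (length(above))
      sum(vapply(a_sz, `[[`, 0, "w")) + 12 * (length(above) - 1) else 0,
    above_h = if (length(above)) max(vapply(a_sz, `[[`, 0, "h")) else 0,
    below_w = if (length(below)) max(vapply(b_sz, `[[`, 0, "w")) else 0,
    below_h = if (length(below))
      sum(vapply(b_sz, `[[`, 0, "h")) + 4 * (length(below) - 1) else 0)
}

# place the two blocks around a horizontal arrow segment [x0,x1] at height yc;
# returns the condition component id (or NULL when there are no items)
.place_cond_horizontal <- function(env, blocks, x0, x1, yc, rotation = 0) {
  items_out <- list()
  mid <- (x0 + x1) / 2
  if (length(blocks$above)) {
    ax <- mid - blocks$above_w / 2
    ytop <- yc - .COND_GAP - blocks$above_h
    for (i in seq_along(blocks$above)) {
      sz <- blocks$a_sz[[i]]
      it <- blocks$above[[i]]
      it$bbox <- bbox(ax, ytop, ax + sz[["w"]], ytop + blocks$above_h)
      it$rotation <- rotation
      items_out[[length(items_out) + 1]] <- it
      if (i < length(blocks$above))
        .add_decoration(env, "comma", ax + sz[["w"]] + 3, yc - .COND_GAP -
                          blocks$above_h / 4, 10)
      ax <- ax + sz[["w"]] + 12
    }
  }
  if (length(blocks$below)) {
    by <- yc + .COND_GAP
    for (i in seq_along(blocks$below)) {
      sz <- blocks$b_sz[[i]]
      it <- blocks$below[[i]]
      it$bbox <- bbox(mid - sz[["w"]] / 2, by, mid + sz[["w"]] / 2,
                      by + sz[["h"]])
      it$rotation <- rotation
      items_out[[length(items_out) + 1]] <- it
      by <- by + sz[["h"]] + 4
    }
  }
  if (!length(items_out)) return(NULL)
  .cond_component_from_items(env, items_out)
}

.cond_component_from_items <- function(env, items_out) {
  xs <- unlist(lapply(items_out, function(it) c(it$bbox$x_min, it$bbox$x_max)))
  ys <- unlist(lapply(items_out, function(it) c(it$bbox$y_min, it$bbox$y_max)))
  .add_component(env, "condition", bbox(min(xs), min(ys), max(xs), max(ys)),
                 items = items_out)
}

# place blocks around an arbitrary straight arrow start->end; agent block on
# the left of travel, others on the right; offsets use the box support
# function so axis-aligned text boxes clear the arrow line
.place_cond_along <- function(env, blocks, start, end, rotation = 0,
                              t_anchor = 0.5) {
  d <- end - start; d <- d / sqrt(sum(d^2))
  nl <- c(d[2], -d[1])          # left of travel
  mid <- start + t_anchor * (end - start)
  items_out <- list()
  put_block <- function(items, szs, w, h, normal) {
    if (!length(items)) return()
    off <- 0.5 * (h * abs(d[1]) + w * abs(d[2])) + 10
    ctr <- mid + normal * (off + 0)
    ytop <- ctr[2] - h / 2
    if (identical(normal, nl)) {   # one line, left-to-right
      ax <- ctr[1] - w / 2
      for (i in seq_along(items)) {
        sz <- szs[[i]]; it <- items[[i]]
        it$bbox <- bbox(ax, ytop, ax + sz[["w"]], ytop + h)
        it$rotation <- rotation
        items_out[[length(items_out) + 1]] <<- it
        ax <- ax + sz[["w"]] + 12
      }
    } else {                       # stacked lines
      by <- ytop
      for (i in seq_along(items)) {
        sz <- szs[[i]]; it <- items[[i]]
        it$bbox <- bbox(ctr[1] - sz[["w"]] / 2, by, ctr[1] + sz[["w"]] / 2,
                        by + sz[["h"]])
        it$rotation <- rotation
        items_out[[length(items_out) + 1]] <<- it
        by <- by + sz[["h"]] + 4
      }
    }
  }
  put_block(blocks$above, blocks$a_sz, blocks$above_w, blocks$above_h, nl)
  put_block(blocks$below, blocks$b_sz, blocks$below_w, blocks$below_h, -nl)
  if (!length(items_out)) return(NULL)
  .cond_component_from_items(env, items_out)
}

# --- abstract-step normalization -------------------------------------------

# branch and cycle draw one molecule per node: surplus reactants migrate to
# the agent field (written above the arrow, as the literature does)
.coerce_single_reactant <- function(st) {
  if (length(st$reactants) > 1) {
    st$agents <- c(st$agents, st$reactants[-1])
    st$reactants <- st$reactants[1]
  }
  st
}

.step_source_smiles <- function(st)
  paste0(paste(st$reactants, collapse = "."), ">",
         paste(st$agents, collapse = "."), ">",
         paste(st$products, collapse = "."))

# SMILES agents become leading agent condition items
.step_items <- function(st) {
  ag <- lapply(st$agents, function(s) condition_item(s, "agent"))
  c(ag, st$conditions %||% list())
}

# --- line-flow engine (single_line, multiple_line rows) ---------------------

# an element: list(w, ha, hb, place(x, yc)); flow places elements left to
# right with wrapping, centering each line on its own baseline
.flow <- function(elements, max_w, y0 = 0) {
  x <- .PAD; y <- y0
  line <- list(); right <- .PAD
  flush <- function() {
    if (!length(line)) return()
    ha <- max(vapply(line, `[[`, 0, "ha"))
    hb <- max(vapply(line, `[[`, 0, "hb"))
    yc <- y + ha
    for (el in line) el$place(el$x, yc)
    y <<- y + ha + hb + .ROW_GAP
    line <<- list(); x <<- .PAD
  }
  for (el in elements) {
    if (identical(el$kind, "break")) { flush(); next }
    if (length(line) && x + el$w > max_w - .PAD) flush()
    el$x <- x
    right <- max(right, x + el$w)
    line[[length(line) + 1]] <- el
    x <- x + el$w + .GAP
  }
  flush()
  list(bottom = y - .ROW_GAP, right = right)
}

.mol_element <- function(env, smiles, role, scale, register) {
  force(register); force(smiles); force(role)
  sz <- .mol_size(smiles, scale)
  list(kind = "mol", w = sz[["w"]], ha = sz[["h"]] / 2, hb = sz[["h"]] / 2,
       place = function(x, yc) {
         id <- .add_component(env, role,
                              bbox(x, yc - sz[["h"]] / 2, x + sz[["w"]],
                                   yc + sz[["h"]] / 2),
                              smiles = smiles)
         register(id)
       })
}

.plus_element <- function(env, fs) {
  s <- max(12, 1.1 * fs)
  list(kind = "plus", w = s, ha = s / 2, hb = s / 2,
       place = function(x, yc) .add_decoration(env, "plus", x + s / 2, yc, s))
}

.arrow_element <- function(env, blocks, fs, line_width, register,
                           rotation = 0) {
  force(register); force(blocks); force(rotation)
  len <- max(80, blocks$above_w + 18, blocks$below_w + 18)
  ha <- .COND_GAP + blocks$above_h + 4
  hb <- .COND_GAP + blocks$below_h + 4
  list(kind = "arrow", w = len, ha = ha, hb = hb,
       place = function(x, yc) {
         arr <- arrow(c(x + 2, yc), c(x + len - 2, yc), "straight")
         cid <- .place_cond_horizontal(env, blocks, x, x + len, yc, rotation)
         register(arr, cid)
       })
}

# --- per-pattern layouts ----------------------------------------------------

.layout_line <- function(env, steps, draw, chained) {
  fs <- draw$font_size
  elements <- list()
  pending <- vector("list", length(steps))   # per-step registration state
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    pending[[k]] <- new.env(parent = emptyenv())
    pending[[k]]$r_ids <- character(0); pending[[k]]$p_ids <- character(0)
    pk <- pending[[k]]
    reuse <- chained && !is.null(st$reuse_reactant_of)
    if (chained && k > 1)
      elements[[length(elements) + 1]] <- list(kind = "break")
    reactants <- st$reactants
    if (reuse) {
      # first reactant is the previous step's (already drawn) product
      pk$reuse_from <- st$reuse_reactant_of
      reactants <- reactants[-1]
    }
    for (j in seq_along(reactants)) {
      if (j > 1) elements[[length(elements) + 1]] <- .plus_element(env, fs)
      elements[[length(elements) + 1]] <- .mol_element(
        env, reactants[j], "reactant", draw$molecule_scale,
        local({ p <- pk; function(id) p$r_ids <- c(p$r_ids, id) }))
    }
    blocks <- .cond_blocks(.step_items(st), fs, draw$text_rotation)
    elements[[length(elements) + 1]] <- .arrow_element(
      env, blocks, fs, draw$line_width,
      local({ p <- pk; function(arr, cid) { p$arrow <- arr; p$cid <- cid } }),
      draw$text_rotation)
    for (j in seq_along(st$products)) {
      if (j > 1) elements[[length(elements) + 1]] <- .plus_element(env, fs)
      elements[[length(elements) + 1]] <- .mol_element(
        env, st$products[j], "product", draw$molecule_scale,
        local({ p <- pk; function(id) p$p_ids <- c(p$p_ids, id) }))
    }
  }
  .flow(elements, draw$canvas_max_width)
  for (k in seq_along(steps)) {
    pk <- pending[[k]]
    r_ids <- pk$r_ids
    if (!is.null(pk$reuse_from))
      r_ids <- c(pending[[pk$reuse_from]]$p_ids[1], r_ids)
    .add_step(env, r_ids, if (is.null(pk$cid)) character(0) else pk$cid,
              pk$p_ids, pk$arrow, .step_source_smiles(steps[[k]]))
  }
}

.layout_branch <- function(env, steps, draw) {
  steps <- lapply(steps, .coerce_single_reactant)
  shared <- steps[[1]]$reactants[1]
  scale <- draw$molecule_scale; fs <- draw$font_size
  m_sz <- .mol_size(shared, scale)
  blocks <- lapply(steps, function(st)
    .cond_blocks(.step_items(st), fs, draw$text_rotation))
  p_sz <- lapply(steps, function(st) .mol_size(st$products[1], scale))
  t_anchor <- 0.72
  # vertical extent a block can claim around its anchor on the arrow chord
  # (slope-dependent clearance bounded by |slope| <= 0.6 by construction)
  ext_up <- vapply(blocks, function(b) 0.3 * b$above_w + b$above_h + 10, 0)
  ext_dn <- vapply(blocks, function(b) 0.3 * b$below_w + b$below_h + 10, 0)
  arm_h <- vapply(seq_along(steps), function(i) {
    nb_up <- if (i < length(steps)) ext_up[i + 1] else 0
    max(p_sz[[i]][["h"]] + .ROW_GAP,
        (ext_dn[i] + nb_up + 16) / t_anchor,
        (ext_up[i] + (if (i > 1) ext_dn[i - 1] else 0) + 16) / t_anchor)
  }, 0)
  total_h <- sum(arm_h)
  arm_dx <- max(220, max(vapply(blocks, function(b)
    max(b$above_w, b$below_w), 0)) + 90,
    total_h / 2 / 0.6)   # keeps every chord slope below 0.6
  m_box <- bbox(0, total_h / 2 - m_sz[["h"]] / 2, m_sz[["w"]],
                total_h / 2 + m_sz[["h"]] / 2)
  m_id <- .add_component(env, "reactant", m_box, smiles = shared)
  y <- 0
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    yc <- y + arm_h[i] / 2
    px0 <- m_sz[["w"]] + arm_dx
    p_box <- bbox(px0, yc - p_sz[[i]][["h"]] / 2, px0 + p_sz[[i]][["w"]],
                  yc + p_sz[[i]][["h"]] / 2)
    p_id <- .add_component(env, "product", p_box, smiles = st$products[1])
    start <- c(m_sz[["w"]] + 8, total_h / 2)
    end <- c(px0 - 8, yc)
    arr <- arrow(start, end, "straight")
    # anchor conditions past the midpoint: arms share a start point, so
    # text near the fan origin would collide across arms
    cid <- .place_cond_vertical(env, blocks[[i]], start, end, t_anchor,
                                draw$text_rotation)
    .add_step(env, m_id, if (is.null(cid)) character(0) else cid, p_id, arr,
              .step_source_smiles(st))
    y <- y + arm_h[i]
  }
}

# place blocks by vertical displacement from a point on the arrow chord:
# for any left-to-right chord this puts agents strictly on the left of
# travel (above) and other roles on the right (below), with clearance
# computed from the chord slope across the block's width
.place_cond_vertical <- function(env, blocks, start, end, t_anchor = 0.5,
                                 rotation = 0) {
  anchor <- start + t_anchor * (end - start)
  slope <- abs((end[2] - start[2]) / (end[1] - start[1]))
  items_out <- list()
  if (length(blocks$above)) {
    bot <- anchor[2] - 0.5 * slope * blocks$above_w - 8
    ax <- anchor[1] - blocks$above_w / 2
    for (i in seq_along(blocks$above)) {
      sz <- blocks$a_sz[[i]]; it <- blocks$above[[i]]
      it$bbox <- bbox(ax, bot - blocks$above_h, ax + sz[["w"]], bot)
      it$rotation <- rotation
      items_out[[length(items_out) + 1]] <- it
      ax <- ax + sz[["w"]] + 12
    }
  }
  if (length(blocks$below)) {
    top <- anchor[2] + 0.5 * slope * blocks$below_w + 8
    by <- top
    for (i in seq_along(blocks$below)) {
      sz <- blocks$b_sz[[i]]; it <- blocks$below[[i]]
      it$bbox <- bbox(anchor[1] - sz[["w"]] / 2, by, anchor[1] + sz[["w"]] / 2,
                      by + sz[["h"]])
      it$rotation <- rotation
      items_out[[length(items_out) + 1]] <- it
      by <- by + sz[["h"]] + 4
    }
  }
  if (!length(items_out)) return(NULL)
  .cond_component_from_items(env, items_out)
}

.layout_cycle <- function(env, steps, draw) {
  steps <- lapply(steps, .coerce_single_reactant)
  n <- length(steps)
  if (n < 3) stop("cycle layout requires >= 3 steps")
  for (i in seq_len(n)) {
    nxt <- steps[[(i %% n) + 1]]
    if (!identical(steps[[i]]$products[1], nxt$reactants[1]))
      stop("cycle steps must chain: product of step ", i,
           " must be the reactant of the next step")
  }
  scale <- draw$molecule_scale; fs <- draw$font_size
  mols <- vapply(steps, function(st) st$reactants[1], character(1))
  sizes <- lapply(mols, .mol_size, scale = scale)
  diag <- vapply(sizes, function(s) sqrt(s[["w"]]^2 + s[["h"]]^2), 0)
  blocks <- lapply(steps, function(st)
    .cond_blocks(.step_items(st), fs, draw$text_rotation))
  inner_w <- max(c(40, vapply(blocks, `[[`, 0, "below_w")))
  inner_h <- max(c(0, vapply(blocks, `[[`, 0, "below_h")))
  sn <- sin(pi / n); cs <- cos(pi / n)
  R <- max(170,
           (max(diag) + 36) / (2 * sn),
           ((inner_w + 16) / (2 * sn) + inner_h / 2 + 14) / cs)
  theta <- -pi / 2 + 2 * pi * (seq_len(n) - 1) / n   # clockwise, start at top
  ctr <- lapply(seq_len(n), function(i)
    c(R * cos(theta[i]), R * sin(theta[i])))
  ids <- character(n)
  for (i in seq_len(n)) {
    s <- sizes[[i]]
    role <- if (i == 1) "reactant" else "product"
    ids[i] <- .add_component(env, role,
                             bbox(ctr[[i]][1] - s[["w"]] / 2,
                                  ctr[[i]][2] - s[["h"]] / 2,
                                  ctr[[i]][1] + s[["w"]] / 2,
                                  ctr[[i]][2] + s[["h"]] / 2),
                             smiles = mols[i])
  }
  for (i in seq_len(n)) {
    j <- (i %% n) + 1
    d_i <- (diag[i] / 2 + 14) / R
    d_j <- (diag[j] / 2 + 14) / R
    a0 <- theta[i] + d_i; a1 <- theta[i] + 2 * pi / n - d_j
    am <- (a0 + a1) / 2
    start <- c(R * cos(a0), R * sin(a0))
    end <- c(R * cos(a1), R * sin(a1))
    control <- list(c(1.25 * R * cos(am), 1.25 * R * sin(am)))
    arr <- arrow(start, end, "curved", control = control)
    # agents outward along the mid-angle, others inward
    cid <- .place_cond_cycle(env, blocks[[i]], R, am, n, draw$text_rotation)
    .add_step(env, ids[i], if (is.null(cid)) character(0) else cid, ids[j],
              arr, .step_source_smiles(steps[[i]]))
  }
}

.place_cond_cycle <- function(env, blocks, R, am, n, rotation = 0) {
  items_out <- list()
  u <- c(cos(am), sin(am))     # outward unit vector at the arc midpoint
  if (length(blocks$above)) {
    # stacked vertically: every item center then stays outside the chord
    stack_h <- sum(vapply(blocks$a_sz, `[[`, 0, "h")) +
      4 * (length(blocks$above) - 1)
    r_out <- 1.12 * R + stack_h / 2 + 10
    ctr <- u * r_out
    by <- ctr[2] - stack_h / 2
    for (i in seq_along(blocks$above)) {
      sz <- blocks$a_sz[[i]]; it <- blocks$above[[i]]
      it$bbox <- bbox(ctr[1] - sz[["w"]] / 2, by, ctr[1] + sz[["w"]] / 2,
                      by + sz[["h"]])
      it$rotation <- rotation
      items_out[[length(items_out) + 1]] <- it
      by <- by + sz[["h"]] + 4
    }
  }
  if (length(blocks$below)) {
    r_in <- R * cos(pi / n) - blocks$below_h / 2 - 14
    ctr <- u * max(r_in, blocks$below_h / 2 + 20)
    by <- ctr[2] - blocks$below_h / 2
    for (i in seq_along(blocks$below)) {
      sz <- blocks$b_sz[[i]]; it <- blocks$below[[i]]
      it$bbox <- bbox(ctr[1] - sz[["w"]] / 2, by, ctr[1] + sz[["w"]] / 2,
                      by + sz[["h"]])
      it$rotation <- rotation
      items_out[[length(items_out) + 1]] <- it
      by <- by + sz[["h"]] + 4
    }
  }
  if (!length(items_out)) return(NULL)
  .cond_component_from_items(env, items_out)
}

# --- entry point ------------------------------------------------------------

#' Lay out a reaction scheme
#'
#' Places molecule boxes, arrows and condition text for one scheme; no pixels
#' are drawn. Input steps are "abstract": lists with `reactants`, `agents`,
#' `products` (SMILES character vectors), optional `conditions` (a list of
#' [condition_item()]s without boxes) and, for chained multiple-line schemes,
#' `reuse_reactant_of` (index of the step whose product is this step's first
#' reactant). Branch and cycle layouts draw one molecule per node; surplus
#' reactant molecules are written above the arrow and move to the agent field
#' of the step's source reaction.
#'
#' @param steps List of abstract steps (see [sample_steps()]).
#' @param pattern Layout pattern; `"cycle"` requires >= 3 chaining steps.
#' @param style An [style_config()] (a concrete draw is sampled) or a draw
#'   from [draw_style()].
#' @param rng An [rng_stream()].
#' @return A validated [reaction_scheme()]; layout failure (e.g. a molecule
#'   wider than `canvas_max_width` at the drawn scale) is an error.
#' @export
layout_scheme <- function(steps, pattern, style = style_config(),
                          rng = rng_stream(1)) {
  pattern <- match.arg(pattern, SCHEME_PATTERNS)
  stopifnot(length(steps) >= 1)
  draw <- if (!is.null(style[["font_size"]])) style
  else draw_style(style, rng_fork(rng, 9001L))
  draw$canvas_max_width <- draw[["canvas_max_width"]] %||% 1024
  # unsatisfiable layout: a single molecule wider than the wrap threshold
  for (st in steps) for (m in c(st$reactants, st$products)) {
    if (.mol_size(m, draw$molecule_scale)[["w"]] >
        draw$canvas_max_width - 2 * .PAD)
      stop("molecule wider than canvas_max_width at drawn scale: ", m)
  }
  env <- .new_env()
  switch(pattern,
         single_line = .layout_line(env, steps, draw, chained = FALSE),
         multiple_line = .layout_line(env, steps, draw, chained = TRUE),
         branch = {
           if (length(steps) < 2) stop("branch layout requires >= 2 arms")
           .layout_branch(env, steps, draw)
         },
         cycle = .layout_cycle(env, steps, draw))
  .finalize_layout(env, pattern, draw)
}

# shift everything into positive coordinates and size the canvas to content
.finalize_layout <- function(env, pattern, draw) {
  xs <- c(); ys <- c()
  for (cmp in env$components) {
    xs <- c(xs, cmp$bbox$x_min, cmp$bbox$x_max)
    ys <- c(ys, cmp$bbox$y_min, cmp$bbox$y_max)
  }
  for (st in env$steps) {
    pts <- c(list(st$arrow$start, st$arrow$end), st$arrow$control %||% list())
    for (p in pts) { xs <- c(xs, p[1]); ys <- c(ys, p[2]) }
  }
  for (d in env$decorations) { xs <- c(xs, d$x); ys <- c(ys, d$y) }
  dx <- .PAD - min(xs); dy <- .PAD - min(ys)
  W <- ceiling(max(xs) + dx + .PAD); H <- ceiling(max(ys) + dy + .PAD)
  sh_box <- function(b) bbox(b$x_min + dx, b$y_min + dy, b$x_max + dx,
                             b$y_max + dy)
  comps <- lapply(env$components, function(cmp) {
    cmp$bbox <- sh_box(cmp$bbox)
    if (!is.null(cmp$items))
      cmp$items <- lapply(cmp$items, function(it) {
        it$bbox <- sh_box(it$bbox); it
      })
    cmp
  })
  steps <- lapply(env$steps, function(st) {
    a <- st$arrow
    a$start <- a$start + c(dx, dy); a$end <- a$end + c(dx, dy)
    if (!is.null(a$control))
      a$control <- lapply(a$control, function(p) p + c(dx, dy))
    st$arrow <- a
    st
  })
  deco <- lapply(env$decorations, function(d) {
    d$x <- d$x + dx; d$y <- d$y + dy; d
  })
  scheme <- reaction_scheme(W, H, unname(comps), steps, pattern,
                            style_draw = draw, decorations = deco)
  v <- validate_scheme(scheme)
  if (nrow(v))
    stop("internal layout error: ", paste(v$rule, collapse = "; "))
  scheme
}

#' Which side of an arrow is a point on?
#'
#' Classifies a point relative to the arrow's travel direction (the chord
#' from start to end): `"agent"` for the left-hand side (above, for a
#' horizontal left-to-right arrow), `"other"` for the right-hand side,
#' `"on"` for points on the line.
#'
#' @param arr An [arrow()].
#' @param point Numeric `c(x, y)`.
#' @return `"agent"`, `"other"` or `"on"`.
#' @export
arrow_side <- function(arr, point) {
  d <- arr$end - arr$start
  p <- point - arr$start
  cr <- d[1] * p[2] - d[2] * p[1]
  if (abs(cr) < 1e-9) "on" else if (cr < 0) "agent" else "other"
}
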