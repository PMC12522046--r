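# Controlled corruption of predictions. Useful for benchmarking an
# evaluator's behaviour and for robustness experiments: starting from ground
# truth, flip roles, jitter boxes, delete or duplicate steps.

.jitter_box <- function(b, sd, W, H) {
  d <- stats::rnorm(4, 0, sd)
  x0 <- max(0, min(b$x_min + d[1], W - 2))
  y0 <- max(0, min(b$y_min + d[2], H - 2))
  x1 <- min(W, max(b$x_max + d[3], x0 + 1))
  y1 <- min(H, max(b$y_max + d[4], y0 + 1))
  bbox(x0, y0, x1, y1)
}

#' Corrupt a scheme to simulate parser errors
#'
#' Applies, independently per step/component: box jitter (Gaussian, clipped
#' to the canvas), relabelling of an agent-bearing condition as a reactant
#' (the soft-match relaxation case), molecule role swaps, step deletion and
#' step duplication.
#'
#' @param scheme A ground-truth [reaction_scheme()].
#' @param rng An [rng_stream()].
#' @param box_jitter_sd Pixel sd of box jitter (0 disables).
#' @param p_agent_as_reactant Probability of moving an agent-bearing
#'   condition component into the step's reactant list.
#' @param p_role_swap Probability of swapping a reactant and a product slot
#'   within a step.
#' @param p_step_delete,p_step_insert Per-step deletion / duplication
#'   probabilities.
#' @return A corrupted copy of the scheme.
#' @export
perturb_scheme <- function(scheme, rng, box_jitter_sd = 3,
                           p_agent_as_reactant = 0.25, p_role_swap = 0.15,
                           p_step_delete = 0.1, p_step_insert = 0.1) {
  W <- scheme$canvas_width; H <- scheme$canvas_height
  with_rng(rng, {
    comps <- scheme$components
    if (box_jitter_sd > 0)
      comps <- lapply(comps, function(cmp) {
        cmp$bbox <- .jitter_box(cmp$bbox, box_jitter_sd, W, H)
        if (!is.null(cmp$items))
          cmp$items <- lapply(cmp$items, function(it) {
            if (!is.null(it$bbox))
              it$bbox <- .jitter_box(it$bbox, box_jitter_sd / 2, W, H)
            it
          })
        cmp
      })
    out <- scheme
    out$components <- comps
    steps <- list()
    for (st in scheme$steps) {
      if (stats::runif(1) < p_step_delete) next
      if (length(st$condition_ids) && stats::runif(1) < p_agent_as_reactant) {
        movable <- Filter(function(id)
          .agent_bearing(scheme_component(out, id)), st$condition_ids)
        if (length(movable)) {
          id <- movable[[1]]
          st$condition_ids <- setdiff(st$condition_ids, id)
          st$reactant_ids <- c(st$reactant_ids, id)
          # the prediction believes this region is a reactant molecule
          out$components <- lapply(out$components, function(cmp) {
            if (identical(as.character(cmp$id), id)) {
              cmp$role <- "reactant"; cmp$smiles <- "*"; cmp$items <- NULL
            }
            cmp
          })
        }
      }
      if (stats::runif(1) < p_role_swap && length(st$reactant_ids) &&
          length(st$product_ids)) {
        r <- st$reactant_ids[1]; p <- st$product_ids[1]
        st$reactant_ids[1] <- p; st$product_ids[1] <- r
      }
      steps[[length(steps) + 1]] <- st
      if (stats::runif(1) < p_step_insert)
        steps[[length(steps) + 1]] <- st
    }
    out$steps <- steps
    out
  })
}
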