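# Scoring a parser's predictions against ground truth. Reaction-level
# matching: a predicted step matches a ground-truth step iff a bijection
# exists between their components under box IoU >= tau and role agreement;
# the soft criterion relaxes exactly one thing — a ground-truth agent-bearing
# condition may be predicted as a reactant. Reported metrics: precision,
# recall, F1 (hard and soft, overall and per layout pattern), a condition
# role identification confusion matrix with per-role P/R/F1, condition OCR
# accuracy and reaction SMILES exact-match accuracy.

f1_score <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

.agent_bearing <- function(cmp) {
  identical(cmp$role, "condition") &&
    any(vapply(cmp$items %||% list(),
               function(it) identical(it$role, "agent"), logical(1)))
}

#' Does a predicted component match a ground-truth component?
#'
#' True iff box IoU reaches the threshold and the roles agree; under the soft
#' criterion a ground-truth agent-bearing condition predicted as a reactant
#' also counts as agreement. Roles default to the components' own role
#' fields; step-level matching passes the step-local roles instead.
#'
#' @param pred,gt [component()]s.
#' @param mode `"hard"` or `"soft"`.
#' @param iou_threshold Box correspondence threshold (default 0.5).
#' @param pred_role,gt_role Role overrides.
#' @return `TRUE` or `FALSE`.
#' @export
component_matches <- function(pred, gt, mode = c("hard", "soft"),
                              iou_threshold = 0.5,
                              pred_role = pred$role, gt_role = gt$role) {
  mode <- match.arg(mode)
  if (bbox_iou(pred$bbox, gt$bbox) < iou_threshold) return(FALSE)
  if (identical(pred_role, gt_role)) return(TRUE)
  identical(mode, "soft") && identical(gt_role, "condition") &&
    identical(pred_role, "reactant") && .agent_bearing(gt)
}

# step-local slots: (role-in-step, component); a component reused across
# lists contributes one slot per occurrence
.step_slots <- function(step, scheme) {
  slot <- function(ids, role) lapply(ids, function(id) {
    cmp <- scheme_component(scheme, id)
    if (is.null(cmp)) stop("unresolved component id in step: ", id)
    list(role = role, cmp = cmp)
  })
  c(slot(step$reactant_ids, "reactant"),
    slot(step$condition_ids, "condition"),
    slot(step$product_ids, "product"))
}

# maximum-cardinality bipartite matching by augmenting paths on a boolean
# adjacency matrix (rows = left vertices); deterministic in input order
.max_bipartite <- function(adj) {
  nl <- nrow(adj); nr <- ncol(adj)
  match_r <- rep(0L, nr)
  try_kuhn <- function(u, seen) {
    for (v in seq_len(nr)) {
      if (adj[u, v] && !seen[v]) {
        seen[v] <- TRUE
        if (match_r[v] == 0L) { match_r[v] <<- u; return(list(TRUE, seen)) }
        res <- try_kuhn(match_r[v], seen)
        seen <- res[[2]]
        if (res[[1]]) { match_r[v] <<- u; return(list(TRUE, seen)) }
      }
    }
    list(FALSE, seen)
  }
  for (u in seq_len(nl)) try_kuhn(u, rep(FALSE, nr))
  match_r
}

#' Does a predicted step match a ground-truth step?
#'
#' True iff the two steps have the same number of components and a bijection
#' exists in which every pair satisfies [component_matches()] under the
#' step-local roles.
#'
#' @param pred_step,gt_step [reaction_step()]s.
#' @param pred_scheme,gt_scheme Their owning schemes.
#' @inheritParams component_matches
#' @return `TRUE` or `FALSE`.
#' @export
step_matches <- function(pred_step, gt_step, pred_scheme, gt_scheme,
                         mode = c("hard", "soft"), iou_threshold = 0.5) {
  mode <- match.arg(mode)
  ps <- .step_slots(pred_step, pred_scheme)
  gs <- .step_slots(gt_step, gt_scheme)
  if (length(ps) != length(gs)) return(FALSE)
  if (!length(ps)) return(TRUE)
  adj <- matrix(FALSE, length(ps), length(gs))
  for (i in seq_along(ps)) for (j in seq_along(gs))
    adj[i, j] <- component_matches(ps[[i]]$cmp, gs[[j]]$cmp, mode,
                                   iou_threshold,
                                   pred_role = ps[[i]]$role,
                                   gt_role = gs[[j]]$role)
  sum(.max_bipartite(adj) > 0L) == length(ps)
}

.match_counts <- function(tp, n_pred, n_gt, mode, iou_threshold,
                          pairs = NULL) {
  p <- if (n_pred == 0) 0 else tp / n_pred
  r <- if (n_gt == 0) 0 else tp / n_gt
  structure(list(tp = tp, fp = n_pred - tp, fn = n_gt - tp,
                 precision = p, recall = r, f1 = f1_score(p, r),
                 pairs = pairs, mode = mode, iou_threshold = iou_threshold),
            class = "rxn_match_result")
}

#' @export
print.rxn_match_result <- function(x, ...) {
  cat(sprintf("%s match (IoU >= %.2f): TP %d FP %d FN %d | P %.3f R %.3f F1 %.3f\n",
              x$mode, x$iou_threshold, x$tp, x$fp, x$fn,
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Match predicted reactions against ground truth (one image)
#'
#' Maximum-cardinality one-to-one matching between predicted and ground-truth
#' steps under [step_matches()]; precision is TP over predictions (0 when
#' there are none), recall TP over ground truth, F1 their harmonic mean.
#'
#' @param pred_scheme,gt_scheme Schemes carrying the steps to compare.
#' @inheritParams component_matches
#' @return An `rxn_match_result` with counts, metrics and matched pairs.
#' @export
match_reactions <- function(pred_scheme, gt_scheme, mode = c("hard", "soft"),
                            iou_threshold = 0.5) {
  mode <- match.arg(mode)
  np <- length(pred_scheme$steps); ng <- length(gt_scheme$steps)
  if (np == 0 || ng == 0)
    return(.match_counts(0, np, ng, mode, iou_threshold,
                         pairs = cbind(pred = integer(0), gt = integer(0))))
  adj <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng))
    adj[i, j] <- step_matches(pred_scheme$steps[[i]], gt_scheme$steps[[j]],
                              pred_scheme, gt_scheme, mode, iou_threshold)
  m <- .max_bipartite(adj)
  pairs <- cbind(pred = m[m > 0L], gt = which(m > 0L))
  .match_counts(nrow(pairs), np, ng, mode, iou_threshold, pairs)
}

.pool_results <- function(results, mode, iou_threshold) {
  tp <- sum(vapply(results, `[[`, 0, "tp"))
  fp <- sum(vapply(results, `[[`, 0, "fp"))
  fn <- sum(vapply(results, `[[`, 0, "fn"))
  .match_counts(tp, tp + fp, tp + fn, mode, iou_threshold)
}

#' Evaluate a dataset of predictions, optionally per layout pattern
#'
#' Micro-averages TP/FP/FN over images; with `by_pattern`, additionally one
#' result per pattern tag (pooled counts equal the sums of per-pattern
#' counts).
#'
#' @param preds,gts Parallel lists of schemes (same images, same order).
#' @param patterns Pattern tag per image; defaults to the gt schemes'.
#' @inheritParams component_matches
#' @return List with `overall` (an `rxn_match_result`) and, if requested,
#'   `per_pattern` (named list).
#' @export
evaluate_by_pattern <- function(preds, gts, patterns = NULL,
                                mode = c("hard", "soft"),
                                iou_threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(length(preds) == length(gts))
  if (is.null(patterns))
    patterns <- vapply(gts, `[[`, "", "pattern")
  bad <- setdiff(unique(patterns), SCHEME_PATTERNS)
  if (length(bad)) stop("unknown pattern tag: ", paste(bad, collapse = ", "))
  per_image <- lapply(seq_along(preds), function(i)
    match_reactions(preds[[i]], gts[[i]], mode, iou_threshold))
  per_pattern <- lapply(split(per_image, factor(patterns, SCHEME_PATTERNS)),
                        function(rs) if (length(rs))
                          .pool_results(rs, mode, iou_threshold) else NULL)
  per_pattern <- Filter(Negate(is.null), per_pattern)
  list(overall = .pool_results(per_image, mode, iou_threshold),
       per_pattern = per_pattern)
}

# --- condition-item pairing and CRI/OCR -------------------------------------

.flatten_items <- function(scheme) {
  out <- list()
  for (cmp in scheme$components)
    if (identical(cmp$role, "condition"))
      out <- c(out, cmp$items)
  out
}

# greedy highest-IoU-first pairing of condition items
.pair_items <- function(pred_items, gt_items, iou_threshold = 0.5) {
  np <- length(pred_items); ng <- length(gt_items)
  pairs <- cbind(pred = integer(0), gt = integer(0))
  if (np && ng) {
    ious <- matrix(0, np, ng)
    for (i in seq_len(np)) for (j in seq_len(ng))
      ious[i, j] <- bbox_iou(pred_items[[i]]$bbox, gt_items[[j]]$bbox)
    repeat {
      best <- which.max(ious)
      if (ious[best] < iou_threshold) break
      i <- (best - 1) %% np + 1; j <- (best - 1) %/% np + 1
      pairs <- rbind(pairs, c(i, j))
      ious[i, ] <- -1; ious[, j] <- -1
    }
  }
  list(pairs = pairs,
       unpaired_pred = setdiff(seq_len(np), pairs[, 1]),
       unpaired_gt = setdiff(seq_len(ng), pairs[, 2]))
}

#' Condition role identification metrics
#'
#' Pairs predicted and ground-truth condition items by box IoU (greedy,
#' highest first) and tabulates role confusion over the six roles. Unpaired
#' ground-truth items fall into a dedicated `missed` column; unpaired
#' predictions are charged as false positives to their predicted role.
#' Accuracy is the diagonal fraction over all ground-truth items.
#'
#' @param pred_items,gt_items Lists of [condition_item()]s with boxes, or
#'   lists of schemes (items are gathered per image).
#' @param iou_threshold Item-box pairing threshold.
#' @return An `rxn_confusion`: list with `matrix` (6 x 7), `accuracy`,
#'   `per_role` (data frame precision/recall/f1), `unpaired_pred` counts.
#' @export
evaluate_cri <- function(pred_items, gt_items, iou_threshold = 0.5) {
  flat <- .normalize_item_input(pred_items, gt_items, iou_threshold)
  m <- matrix(0L, 6, 7, dimnames = list(gt = CONDITION_ROLES,
                                        pred = c(CONDITION_ROLES, "missed")))
  unpaired_pred <- stats::setNames(integer(6), CONDITION_ROLES)
  for (im in flat) {
    pr <- im$pairs
    for (k in seq_len(nrow(pr$pairs))) {
      g <- im$gt[[pr$pairs[k, 2]]]$role
      p <- im$pred[[pr$pairs[k, 1]]]$role
      m[g, p] <- m[g, p] + 1L
    }
    for (j in pr$unpaired_gt) {
      g <- im$gt[[j]]$role
      m[g, "missed"] <- m[g, "missed"] + 1L
    }
    for (i in pr$unpaired_pred) {
      p <- im$pred[[i]]$role
      unpaired_pred[p] <- unpaired_pred[p] + 1L
    }
  }
  total <- sum(m)
  acc <- if (total == 0) NA_real_ else sum(diag(m[, 1:6])) / total
  per_role <- do.call(rbind, lapply(CONDITION_ROLES, function(r) {
    tp <- m[r, r]
    fn <- sum(m[r, ]) - tp
    fp <- sum(m[, r]) - tp + unpaired_pred[[r]]
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
    data.frame(role = r, precision = p, recall = rc, f1 = f1_score(p, rc))
  }))
  structure(list(matrix = m, accuracy = acc, per_role = per_role,
                 unpaired_pred = unpaired_pred, n = total),
            class = "rxn_confusion")
}

#' @export
print.rxn_confusion <- function(x, ...) {
  cat(sprintf("CRI accuracy %.3f over %d items\n", x$accuracy, x$n))
  print(x$matrix)
  invisible(x)
}

# accept either flat item lists (single image) or lists of schemes
.normalize_item_input <- function(pred, gt, iou_threshold) {
  is_schemes <- length(gt) && inherits(gt[[1]], "rxn_scheme")
  if (is_schemes) {
    stopifnot(length(pred) == length(gt))
    lapply(seq_along(gt), function(i) {
      pi <- .flatten_items(pred[[i]]); gi <- .flatten_items(gt[[i]])
      list(pred = pi, gt = gi, pairs = .pair_items(pi, gi, iou_threshold))
    })
  } else {
    list(list(pred = pred, gt = gt,
              pairs = .pair_items(pred, gt, iou_threshold)))
  }
}

#' Normalize condition text for OCR comparison
#'
#' Unicode NFKC, all whitespace stripped, degree-of-Celsius variants unified
#' (`35C`, `35 °C` and `35℃` compare equal).
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_condition_text <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  x <- gsub("℃", "°C", x)     # ℃ -> °C
  x <- gsub("\\s+", "", x)
  gsub("°", "", x)                 # drop the degree sign
}

#' Condition OCR accuracy
#'
#' Fraction of IoU-paired condition items whose normalized texts are
#' identical (see [normalize_condition_text()]).
#'
#' @inheritParams evaluate_cri
#' @return Fraction in `[0, 1]` (NA when nothing pairs); attribute `n` holds
#'   the number of paired items.
#' @export
ocr_accuracy <- function(pred_items, gt_items, iou_threshold = 0.5) {
  flat <- .normalize_item_input(pred_items, gt_items, iou_threshold)
  hits <- 0L; n <- 0L
  for (im in flat) {
    for (k in seq_len(nrow(im$pairs$pairs))) {
      p <- im$pred[[im$pairs$pairs[k, 1]]]$text
      g <- im$gt[[im$pairs$pairs[k, 2]]]$text
      n <- n + 1L
      if (identical(normalize_condition_text(p),
                    normalize_condition_text(g)))
        hits <- hits + 1L
    }
  }
  structure(if (n == 0) NA_real_ else hits / n, n = n)
}

# --- reaction SMILES accuracy -----------------------------------------------

#' Reactions of a scheme as reaction SMILES
#'
#' Expands bidirectional arrows, drops crossed-out steps and assembles one
#' reaction SMILES per remaining step.
#'
#' @param scheme An [reaction_scheme()].
#' @return Character vector of reaction SMILES.
#' @export
scheme_reactions <- function(scheme) {
  ex <- expand_bidirectional(scheme)
  vapply(ex$steps, assemble_reaction_smiles, character(1), scheme = ex)
}

#' Reaction SMILES exact-match accuracy
#'
#' Fraction of images whose full predicted reaction set equals the ground
#' truth under [reaction_equal()], order-insensitively across steps.
#' Unparseable predictions count as non-matches (with a warning).
#'
#' @param pred_reactions,gt_reactions Parallel lists; each element is the
#'   character vector of reaction SMILES of one image.
#' @param include_agents Compare agent fields too?
#' @return Fraction in `[0, 1]`.
#' @export
smiles_exact_match_accuracy <- function(pred_reactions, gt_reactions,
                                        include_agents = FALSE) {
  stopifnot(length(pred_reactions) == length(gt_reactions))
  keyset <- function(rxns, lab)
    sort(unname(vapply(rxns, .reaction_key, character(1),
                       include_agents = include_agents, label = lab)))
  hits <- vapply(seq_along(gt_reactions), function(i) {
    pk <- tryCatch(keyset(pred_reactions[[i]], "prediction"),
                   error = function(e) {
                     warning("image ", i, ": ", conditionMessage(e),
                             call. = FALSE)
                     NULL
                   })
    if (is.null(pk)) return(FALSE)
    identical(pk, keyset(gt_reactions[[i]], "ground truth"))
  }, logical(1))
  mean(hits)
}

# --- one-call report --------------------------------------------------------

#' Full metrics report for a prediction set
#'
#' Computes hard and soft reaction-level metrics (overall and per pattern),
#' CRI, condition OCR and reaction SMILES exact-match accuracy in one pass.
#'
#' @param preds,gts Parallel lists of schemes.
#' @param iou_threshold Box correspondence threshold.
#' @param include_agents Agent-field flag for SMILES accuracy.
#' @return An `rxn_metrics_report` list.
#' @export
evaluate_dataset <- function(preds, gts, iou_threshold = 0.5,
                             include_agents = FALSE) {
  hard <- evaluate_by_pattern(preds, gts, mode = "hard",
                              iou_threshold = iou_threshold)
  soft <- evaluate_by_pattern(preds, gts, mode = "soft",
                              iou_threshold = iou_threshold)
  cri <- evaluate_cri(preds, gts, iou_threshold)
  ocr <- ocr_accuracy(preds, gts, iou_threshold)
  smiles <- smiles_exact_match_accuracy(lapply(preds, scheme_reactions),
                                        lapply(gts, scheme_reactions),
                                        include_agents)
  structure(list(hard = hard, soft = soft, cri = cri,
                 ocr_accuracy = as.numeric(ocr), ocr_n = attr(ocr, "n"),
                 smiles_exact_match = smiles,
                 iou_threshold = iou_threshold, n_images = length(gts)),
            class = "rxn_metrics_report")
}

#' @export
print.rxn_metrics_report <- function(x, ...) {
  cat("Reaction-image parsing metrics over", x$n_images, "images\n")
  print(x$hard$overall); print(x$soft$overall)
  cat(sprintf("CRI accuracy: %.3f | OCR accuracy: %.3f | SMILES exact match: %.3f\n",
              x$cri$accuracy, x$ocr_accuracy, x$smiles_exact_match))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report An `rxn_metrics_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  strip <- function(r) r[c("tp", "fp", "fn", "precision", "recall", "f1")]
  out <- list(
    n_images = report$n_images, iou_threshold = report$iou_threshold,
    hard = c(list(overall = strip(report$hard$overall)),
             list(per_pattern = lapply(report$hard$per_pattern, strip))),
    soft = c(list(overall = strip(report$soft$overall)),
             list(per_pattern = lapply(report$soft$per_pattern, strip))),
    cri = list(accuracy = report$cri$accuracy,
               confusion = as.data.frame.matrix(report$cri$matrix),
               per_role = report$cri$per_role),
    ocr_accuracy = report$ocr_accuracy,
    smiles_exact_match = report$smiles_exact_match)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
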