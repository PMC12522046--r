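# Evaluator: component/step/reaction matching, CRI, OCR, SMILES accuracy.

test_that("component matching needs box IoU and role agreement", {
  a <- component("a", "reactant", bbox(0, 0, 100, 100), smiles = "C")
  expect_true(component_matches(a, a, "hard"))
  expect_true(component_matches(a, a, "soft"))
  far <- component("b", "reactant", bbox(200, 200, 300, 300), smiles = "C")
  expect_false(component_matches(far, a, "hard"))
  expect_false(component_matches(far, a, "soft"))
  prod <- component("c", "product", bbox(0, 0, 100, 100), smiles = "C")
  expect_false(component_matches(prod, a, "hard"))
  expect_false(component_matches(prod, a, "soft"))
})

test_that("only a gt agent may be relabelled reactant, and only under soft", {
  gt_agent <- component("g", "condition", bbox(0, 0, 100, 50),
                        items = list(condition_item("H2", "agent",
                                                    bbox(0, 0, 100, 50))))
  gt_solvent <- component("g2", "condition", bbox(0, 0, 100, 50),
                          items = list(condition_item("THF", "solvent",
                                                      bbox(0, 0, 100, 50))))
  pred <- component("p", "reactant", bbox(0, 0, 100, 50), smiles = "*")
  expect_false(component_matches(pred, gt_agent, "hard"))
  expect_true(component_matches(pred, gt_agent, "soft"))
  expect_false(component_matches(pred, gt_solvent, "soft"))
})

test_that("step matching requires a complete component bijection", {
  gt <- make_simple_scheme()
  expect_true(step_matches(gt$steps[[1]], gt$steps[[1]], gt, gt, "hard"))
  missing_prod <- gt
  missing_prod$steps[[1]]$product_ids <- character(0)
  expect_false(step_matches(missing_prod$steps[[1]], gt$steps[[1]],
                            missing_prod, gt, "hard"))
  moved <- agents_as_reactants(gt)
  expect_false(step_matches(moved$steps[[1]], gt$steps[[1]], moved, gt,
                            "hard"))
  expect_true(step_matches(moved$steps[[1]], gt$steps[[1]], moved, gt,
                           "soft"))
})

test_that("precision, recall and F1 follow the matching counts", {
  gt <- make_simple_scheme()
  res <- match_reactions(gt, gt, "hard")
  expect_identical(c(res$precision, res$recall, res$f1), c(1, 1, 1))

  # 3 gt steps, 2 predictions of which 1 matches: P = 1/2, R = 1/3, F1 = 0.4
  gt3 <- gt
  shift <- function(s, dx) {
    s$components <- lapply(s$components, function(cmp) {
      cmp$bbox <- bbox(cmp$bbox$x_min + dx, cmp$bbox$y_min,
                       cmp$bbox$x_max + dx, cmp$bbox$y_max)
      if (!is.null(cmp$items))
        cmp$items <- lapply(cmp$items, function(it) {
          it$bbox <- bbox(it$bbox$x_min + dx, it$bbox$y_min,
                          it$bbox$x_max + dx, it$bbox$y_max); it })
      cmp$id <- paste0(cmp$id, "_", dx); cmp
    })
    s$steps <- lapply(s$steps, function(st) {
      st$reactant_ids <- paste0(st$reactant_ids, "_", dx)
      st$condition_ids <- paste0(st$condition_ids, "_", dx)
      st$product_ids <- paste0(st$product_ids, "_", dx)
      st$arrow$start <- st$arrow$start + c(dx, 0)
      st$arrow$end <- st$arrow$end + c(dx, 0); st })
    s
  }
  a <- shift(gt, 0); b <- shift(gt, 1000); c3 <- shift(gt, 2000)
  gt3$components <- c(a$components, b$components, c3$components)
  gt3$steps <- c(a$steps, b$steps, c3$steps)
  gt3$canvas_width <- 3000
  pred <- gt3
  pred$steps <- pred$steps[1:2]
  # break prediction 2 by dropping its product
  pred$steps[[2]]$product_ids <- character(0)
  res2 <- match_reactions(pred, gt3, "hard")
  expect_identical(res2$tp, 1L)
  expect_equal(res2$precision, 0.5)
  expect_equal(res2$recall, 1 / 3)
  expect_equal(res2$f1, 0.4)

  empty <- gt; empty$steps <- list()
  res3 <- match_reactions(empty, gt, "hard")
  expect_identical(c(res3$precision, res3$recall, res3$f1), c(0, 0, 0))
})

test_that("matching is invariant to the order of the step lists", {
  gts <- lapply(1:4, gen_scheme, seed = 61)
  preds <- lapply(seq_along(gts), function(i)
    perturb_scheme(gts[[i]], rng_fork(rng_stream(99), i)))
  for (i in seq_along(gts)) {
    base <- match_reactions(preds[[i]], gts[[i]], "hard")
    shuffled <- preds[[i]]
    shuffled$steps <- rev(shuffled$steps)
    res <- match_reactions(shuffled, gts[[i]], "hard")
    expect_identical(res$tp, base$tp)
    expect_identical(res$f1, base$f1)
  }
})

test_that("augmenting-path matching equals brute force on small instances", {
  for (i in 1:30) {
    set.seed(i)
    nr <- sample(1:4, 1); nc <- sample(1:4, 1)
    adj <- matrix(stats::runif(nr * nc) < 0.4, nr, nc)
    got <- sum(rxnsketch:::.max_bipartite(adj) > 0)
    expect_identical(got, as.integer(brute_force_matching(adj)))
  }
})

test_that("per-pattern pooling is additive over disjoint pattern groups", {
  gts <- lapply(1:6, gen_scheme, seed = 71)
  preds <- lapply(seq_along(gts), function(i)
    perturb_scheme(gts[[i]], rng_fork(rng_stream(31), i)))
  both <- evaluate_by_pattern(preds, gts, mode = "hard")
  tp_sum <- sum(vapply(both$per_pattern, `[[`, 0, "tp"))
  fn_sum <- sum(vapply(both$per_pattern, `[[`, 0, "fn"))
  expect_identical(tp_sum, as.numeric(both$overall$tp))
  expect_identical(fn_sum, as.numeric(both$overall$fn))
  expect_error(evaluate_by_pattern(preds, gts, patterns = rep("spiral", 6)),
               "unknown pattern")
  single <- evaluate_by_pattern(preds[1], gts[1], mode = "hard")
  expect_identical(single$per_pattern[[gts[[1]]$pattern]]$f1,
                   single$overall$f1)
})

test_that("CRI confusion counts hand-checked cases", {
  mk <- function(role, x, text = "t")
    condition_item(text, role, bbox(x, 0, x + 40, 20))
  gt <- list(mk("agent", 0), mk("solvent", 100), mk("temperature", 200),
             mk("time", 300), mk("yield", 400))
  ident <- evaluate_cri(gt, gt)
  expect_identical(ident$accuracy, 1)
  expect_identical(sum(diag(ident$matrix[, 1:6])), 5L)

  pred <- gt
  pred[[2]] <- mk("agent", 100)   # solvent predicted as agent
  conf <- evaluate_cri(pred, gt)
  expect_identical(conf$accuracy, 0.8)
  expect_identical(conf$matrix["solvent", "agent"], 1L)
  expect_identical(conf$matrix["agent", "agent"], 1L)

  # unpaired gt lands in the missed column; unpaired pred charges precision
  conf2 <- evaluate_cri(pred[1:4], gt)
  expect_identical(conf2$matrix["yield", "missed"], 1L)
  extra <- c(pred, list(mk("agent", 800)))
  conf3 <- evaluate_cri(extra, gt)
  expect_identical(unname(conf3$unpaired_pred["agent"]), 1L)
  agent_row <- conf3$per_role[conf3$per_role$role == "agent", ]
  expect_lt(agent_row$precision, 1)
})

test_that("OCR accuracy normalizes degrees, whitespace and unicode forms", {
  expect_identical(normalize_condition_text("35 °C"), "35C")
  expect_identical(normalize_condition_text("35℃"), "35C")
  expect_identical(normalize_condition_text("35C"), "35C")
  mk <- function(text, x) condition_item(text, "temperature",
                                         bbox(x, 0, x + 40, 20))
  gt <- list(mk("35 °C", 0), mk("THF", 100))
  pred_ok <- list(mk("35C", 0), mk("THF", 100))
  expect_identical(as.numeric(ocr_accuracy(pred_ok, gt)), 1)
  pred_bad <- list(mk("35C", 0), mk("DMF", 100))
  expect_identical(as.numeric(ocr_accuracy(pred_bad, gt)), 0.5)
})

test_that("SMILES exact match scores whole images, order-insensitively", {
  gt <- list(c("CCO>>CC=O", "CC=O>>CC(=O)O"), "CCBr.N>>CCN")
  pred_same <- list(c("CC=O>>CC(=O)O", "OCC>>O=CC"), "N.CCBr>>CCN")
  expect_identical(smiles_exact_match_accuracy(pred_same, gt), 1)
  pred_half <- list(c("CCO>>CC=O", "CC=O>>CC(=O)O"), "CCBr.N>>CCO")
  expect_identical(smiles_exact_match_accuracy(pred_half, gt), 0.5)
  pred_broken <- list(c("CCO>>CC=O", "CC=O>>CC(=O)O"), "xx((>>C")
  expect_warning(
    acc <- smiles_exact_match_accuracy(pred_broken, gt), "parse")
  expect_identical(acc, 0.5)
})

test_that("ground truth scored against itself is perfect on all levels", {
  gts <- lapply(1:5, gen_scheme, seed = 81)
  rep <- evaluate_dataset(gts, gts)
  expect_identical(rep$hard$overall$f1, 1)
  expect_identical(rep$soft$overall$f1, 1)
  expect_identical(rep$cri$accuracy, 1)
  expect_identical(rep$ocr_accuracy, 1)
  expect_identical(rep$smiles_exact_match, 1)
})

test_that("soft-mode F1 never drops below hard-mode F1", {
  gts <- lapply(1:10, gen_scheme, seed = 91)
  for (i in seq_along(gts)) {
    pred <- perturb_scheme(gts[[i]], rng_fork(rng_stream(17), i))
    hard <- match_reactions(pred, gts[[i]], "hard")
    soft <- match_reactions(pred, gts[[i]], "soft")
    expect_gte(soft$f1, hard$f1)
  }
})
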