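# Token codec: quantization arithmetic, block structure, round trips,
# decoder totality.

test_that("coordinate quantization follows round(c / extent * (B - 1))", {
  b <- bbox(0, 0, 250, 100)
  q <- quantize_bbox(b, 1000, 400, 1000)
  # 250/1000 * 999 = 249.75 -> 250; 100/400 * 999 = 249.75 -> 250
  expect_identical(q, c(0L, 0L, 250L, 250L))
  expect_identical(q[1], 0L)                      # origin corner
  full <- quantize_bbox(bbox(0, 0, 1000, 400), 1000, 400, 1000)
  expect_identical(full[3], 999L)                 # x = canvas width -> B - 1
  expect_identical(full[4], 999L)
  expect_error(quantize_bbox(bbox(0, 0, 1200, 100), 1000, 400, 1000),
               "outside canvas")
})

test_that("dequantization inverts within half a bin", {
  for (B in c(100, 500, 1000)) {
    b <- bbox(13.7, 21.2, 801.9, 399.4)
    q <- quantize_bbox(b, 1024, 400, B)
    d <- dequantize_bbox(q, 1024, 400, B)
    expect_lte(abs(d$x_min - b$x_min), 1024 / (2 * (B - 1)) + 1e-9)
    expect_lte(abs(d$y_max - b$y_max), 400 / (2 * (B - 1)) + 1e-9)
  }
})

test_that("a minimal scheme encodes to the expected block structure", {
  comps <- list(
    component("r", "reactant", bbox(0, 0, 50, 50), smiles = "CCO"),
    component("p", "product", bbox(100, 0, 150, 50), smiles = "CC=O"))
  st <- reaction_step("r", character(0), "p", arrow(c(55, 25), c(95, 25)))
  s <- reaction_scheme(200, 60, comps, list(st), "single_line")
  toks <- encode_scheme(s, 1000)
  expect_length(toks, 2 + 6 + 6)   # RXN pair + (RCT + 4 + end) + (PRD + ...)
  expect_identical(sum(toks == "RXN_START"), 1L)
  expect_identical(sum(toks == "RCT_START"), 1L)
  expect_identical(sum(toks == "PRD_START"), 1L)
  expect_identical(sum(!is.na(suppressWarnings(as.integer(toks)))), 8L)
})

test_that("role tokens appear for the five roles but never for 'other'", {
  s <- make_simple_scheme(agent_texts = "H2")
  s$components[[2]]$items <- c(
    s$components[[2]]$items,
    list(condition_item("pH 10–11", "other", bbox(160, 85, 240, 105))))
  toks <- encode_scheme(s, 1000)
  expect_identical(sum(toks == "[Age]"), 1L)
  expect_identical(sum(toks == "[Sol]"), 1L)
  # 3 items but only 2 role tokens: 'other' carries none
  role_toks <- sum(toks %in% c("[Age]", "[Sol]", "[Tem]", "[Time]", "[Yld]"))
  expect_identical(role_toks, 2L)
  dec <- decode_tokens(toks)
  cnd <- Filter(function(cm) identical(cm$role, "condition"),
                dec$scheme$components)[[1]]
  expect_identical(vapply(cnd$items, `[[`, "", "role"),
                   c("agent", "solvent", "other"))
  expect_identical(vapply(cnd$items, `[[`, "", "text"),
                   c("H2", "THF", "pH 10–11"))
})

test_that("encode/decode round-trips roles, texts and boxes within half a bin", {
  for (i in 1:12) {
    s <- gen_scheme(i, seed = 41)
    ord <- rxnsketch:::.step_order(s)
    for (B in c(100, 500, 1000)) {
      dec <- decode_tokens(encode_scheme(s, B))
      expect_identical(nrow(dec$diagnostics), 0L)
      expect_length(dec$scheme$steps, length(s$steps))
      tol_x <- s$canvas_width / (2 * (B - 1)) + 1e-9
      tol_y <- s$canvas_height / (2 * (B - 1)) + 1e-9
      for (k in seq_along(ord)) {
        gt_st <- s$steps[[ord[k]]]; dc_st <- dec$scheme$steps[[k]]
        expect_length(dc_st$reactant_ids, length(gt_st$reactant_ids))
        expect_length(dc_st$condition_ids, length(gt_st$condition_ids))
        expect_length(dc_st$product_ids, length(gt_st$product_ids))
        pairs <- list(c("reactant_ids", "reactant_ids"),
                      c("condition_ids", "condition_ids"),
                      c("product_ids", "product_ids"))
        for (pr in pairs) {
          for (j in seq_along(gt_st[[pr[1]]])) {
            g <- scheme_component(s, gt_st[[pr[1]]][j])
            d <- scheme_component(dec$scheme, dc_st[[pr[2]]][j])
            expect_lte(abs(g$bbox$x_min - d$bbox$x_min), tol_x)
            expect_lte(abs(g$bbox$x_max - d$bbox$x_max), tol_x)
            expect_lte(abs(g$bbox$y_min - d$bbox$y_min), tol_y)
            expect_lte(abs(g$bbox$y_max - d$bbox$y_max), tol_y)
            if (identical(g$role, "condition")) {
              expect_identical(vapply(d$items, `[[`, "", "role"),
                               vapply(g$items, `[[`, "", "role"))
              expect_identical(vapply(d$items, `[[`, "", "text"),
                               vapply(g$items, `[[`, "", "text"))
            }
          }
        }
      }
    }
  }
})

test_that("encoded length is a function of the component/item counts", {
  for (i in 1:6) {
    s <- gen_scheme(i, seed = 43)
    toks <- encode_scheme(s)
    n_comp_slots <- sum(vapply(s$steps, function(st)
      length(st$reactant_ids) + length(st$condition_ids) +
        length(st$product_ids), 0))
    n_items <- sum(vapply(s$steps, function(st)
      sum(vapply(st$condition_ids, function(id)
        length(scheme_component(s, id)$items), 0)), 0))
    n_role_toks <- sum(vapply(all_items(s), function(it)
      !identical(it$role, "other"), logical(1)))
    expect_length(toks, 2 * length(s$steps) + 6 * n_comp_slots +
                    n_items + n_role_toks)
  }
})

test_that("the decoder is total on malformed input", {
  dec <- decode_tokens(character(0))
  expect_length(dec$scheme$steps, 0)
  expect_gt(nrow(dec$diagnostics), 0)

  trunc <- c("RXN_START", "RCT_START", "5", "5", "80", "90")
  dec2 <- decode_tokens(trunc, 1000, 1000, 1000)
  expect_true(any(grepl("unclosed", dec2$diagnostics$issue)))

  for (i in 1:60) {
    set.seed(i)
    pool <- c(unlist(rxn_vocabulary(50)$structural), "[Age]", "[Sol]",
              as.character(0:60), "garbage", "H2", "\\[weird")
    junk <- sample(pool, sample(1:40, 1), replace = TRUE)
    expect_no_error(decode_tokens(junk, 500, 500, 50))
  }
})

test_that("texts with spaces and bracket prefixes survive the token stream", {
  s <- make_simple_scheme(agent_texts = "H2")
  s$components[[2]]$items[[2]] <-
    condition_item("[M] buffer 2 h", "other", bbox(175, 110, 225, 130))
  dec <- decode_tokens(encode_scheme(s, 1000))
  cnd <- Filter(function(cm) identical(cm$role, "condition"),
                dec$scheme$components)[[1]]
  expect_true("[M] buffer 2 h" %in% vapply(cnd$items, `[[`, "", "text"))
})

test_that("token streams round-trip through files", {
  toks <- lapply(1:3, function(i) encode_scheme(gen_scheme(i, seed = 47)))
  f <- tempfile(fileext = ".tok")
  write_tokens(toks, f)
  back <- read_tokens(f)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(as.character(back[[i]]), as.character(toks[[i]]))
    expect_identical(attr(back[[i]], "n_bins"), attr(toks[[i]], "n_bins"))
  }
})
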