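# Generator: condition sampling, style draws, layout geometry, rendering.

test_that("condition sampling honours presence probabilities and vocabularies", {
  spec <- condition_spec(p_role_present = c(agent = 1, solvent = 0,
                                            temperature = 0, time = 0,
                                            yield = 0),
                         p_other = 0, p_second_agent = 0,
                         agent_vocab = c("H2", "PdC"))
  for (i in 1:20) {
    items <- sample_conditions(rng_fork(rng_stream(3), i), spec)
    expect_length(items, 1)
    expect_identical(items[[1]]$role, "agent")
    expect_true(items[[1]]$text %in% c("H2", "PdC"))
  }

  none <- condition_spec(p_role_present = c(agent = 0, solvent = 0,
                                            temperature = 0, time = 0,
                                            yield = 0), p_other = 0)
  expect_length(sample_conditions(rng_stream(1), none), 0)
})

test_that("degenerate yield range realizes its format verbatim", {
  spec <- condition_spec(p_role_present = c(agent = 0, solvent = 0,
                                            temperature = 0, time = 0,
                                            yield = 1),
                         p_other = 0, yield_range = c(85, 85))
  items <- sample_conditions(rng_stream(7), spec)
  expect_identical(items[[1]]$text, "85%")
  expect_identical(items[[1]]$role, "yield")
})

test_that("an empty vocabulary with positive presence probability is rejected", {
  expect_error(condition_spec(agent_vocab = character(0)), "agent_vocab")
})

test_that("style draws stay inside their ranges and respect one-hot weights", {
  point <- style_config(font_size_range = c(12, 12),
                        line_width_range = c(2, 2),
                        molecule_scale_range = c(25, 25),
                        pattern_weights = c(single_line = 0, multiple_line = 0,
                                            branch = 0, cycle = 1))
  d <- draw_style(point, rng_stream(5))
  expect_identical(d$font_size, 12)
  expect_identical(d$line_width, 2)
  expect_identical(d$molecule_scale, 25)
  expect_identical(d$pattern, "cycle")
})

test_that("font-size draws are uniform over their range", {
  style <- style_config(font_size_range = c(8, 16))
  draws <- vapply(1:3000, function(i)
    draw_style(style, rng_fork(rng_stream(99), i))$font_size, 0)
  expect_gte(min(draws), 8)
  expect_lte(max(draws), 16)
  se <- sqrt(8^2 / 12) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 12), 3 * se)
})

test_that("same stream, same draws: generation is reproducible", {
  s1 <- gen_scheme(4, seed = 777)
  s2 <- gen_scheme(4, seed = 777)
  expect_identical(scheme_to_record(s1), scheme_to_record(s2))
  s3 <- gen_scheme(5, seed = 777)
  expect_false(identical(scheme_to_record(s1), scheme_to_record(s3)))
})

test_that("agents sit above the arrow and the other roles below it", {
  s <- gen_scheme(1, pattern = "single_line")
  items_seen <- 0
  for (st in s$steps) for (id in st$condition_ids) {
    cmp <- Filter(function(cm) identical(as.character(cm$id), id),
                  s$components)[[1]]
    for (it in cmp$items) {
      items_seen <- items_seen + 1
      ctr <- c((it$bbox$x_min + it$bbox$x_max) / 2,
               (it$bbox$y_min + it$bbox$y_max) / 2)
      side <- arrow_side(st$arrow, ctr)
      if (identical(it$role, "agent")) {
        expect_identical(side, "agent")
        expect_lt(ctr[2], st$arrow$start[2])   # horizontal arrow: above
      } else {
        expect_identical(side, "other")
        expect_gt(ctr[2], st$arrow$start[2])
      }
    }
  }
  expect_gt(items_seen, 0)
})

test_that("an oversized product wraps onto a continuation line", {
  style <- style_config(canvas_max_width = 360,
                        molecule_scale_range = c(26, 26),
                        font_size_range = c(12, 12),
                        line_width_range = c(1, 1),
                        pattern_weights = c(single_line = 1, multiple_line = 0,
                                            branch = 0, cycle = 0))
  steps <- list(list(reactants = "CCO", agents = character(0),
                     products = "CCCCCCCCC(=O)OCC",  # wide at scale 26
                     conditions = list()))
  s <- layout_scheme(steps, "single_line", style, rng_stream(2))
  expect_identical(nrow(validate_scheme(s)), 0L)
  r_box <- s$components[[1]]$bbox
  p <- Filter(function(cm) identical(cm$role, "product"), s$components)[[1]]
  expect_gt(p$bbox$y_min, r_box$y_max)  # pushed to the line below
  expect_lte(s$canvas_width, 360)
})

test_that("cycle layouts close the loop with arrows between consecutive nodes", {
  s <- gen_scheme(2, pattern = "cycle")
  mols <- molecule_components(s)
  n <- length(mols)
  expect_gte(n, 3)
  expect_length(s$steps, n)
  centers <- t(vapply(mols, function(cm) {
    c((cm$bbox$x_min + cm$bbox$x_max) / 2, (cm$bbox$y_min + cm$bbox$y_max) / 2)
  }, numeric(2)))
  centroid <- colMeans(centers)
  radii <- sqrt(rowSums(sweep(centers, 2, centroid)^2))
  expect_lt(diff(range(radii)) / mean(radii), 0.35)  # near-circular
  # each step's product is the next step's reactant, closing the loop
  for (i in seq_len(n)) {
    nxt <- s$steps[[(i %% n) + 1]]
    expect_identical(s$steps[[i]]$product_ids[1], nxt$reactant_ids[1])
    expect_identical(s$steps[[i]]$arrow$kind, "curved")
  }
})

test_that("branch layouts fan out from one shared reactant", {
  s <- gen_scheme(3, pattern = "branch")
  shared <- unique(vapply(s$steps, function(st) st$reactant_ids[1],
                          character(1)))
  expect_length(shared, 1)
  expect_gte(length(s$steps), 2)
})

test_that("molecule boxes never overlap within a scheme", {
  for (i in 1:25) {
    s <- gen_scheme(i, seed = 31)
    mols <- molecule_components(s)
    if (length(mols) < 2) next
    for (a in 1:(length(mols) - 1)) for (b in (a + 1):length(mols))
      expect_identical(bbox_iou(mols[[a]]$bbox, mols[[b]]$bbox), 0)
  }
})

test_that("rendering re-measures boxes tightly and deterministically", {
  s <- gen_scheme(6, pattern = "single_line")
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  r1 <- render_scheme(s, f1)
  r2 <- render_scheme(s, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(scheme_to_record(r1$scheme), scheme_to_record(r2$scheme))
  for (cmp in r1$scheme$components) {
    b <- cmp$bbox
    expect_gt(b$x_max - b$x_min, 0)
    expect_gt(b$y_max - b$y_min, 0)
    expect_lte(b$x_max, r1$scheme$canvas_width)
    expect_lte(b$y_max, r1$scheme$canvas_height)
    # tight boxes never grow beyond the allocated box by more than the pad
    orig <- Filter(function(cm) identical(cm$id, cmp$id), s$components)[[1]]
    expect_lte(abs(b$x_min - orig$bbox$x_min), orig$bbox$x_max)
  }
  expect_identical(nrow(validate_scheme(r1$scheme)), 0L)
})

test_that("renders succeed at both extremes of every augmentation range", {
  style <- style_config()
  for (pick in list(`1` = 1, `2` = 2)) {
    d <- list(font_size = style$font_size_range[[pick]],
              line_width = style$line_width_range[[pick]],
              molecule_scale = style$molecule_scale_range[[pick]],
              pattern = "single_line", text_rotation = 0,
              canvas_max_width = style$canvas_max_width)
    steps <- sample_steps(toy_reaction_source(), "single_line", 1,
                          rng_stream(8))
    steps[[1]]$conditions <- sample_conditions(rng_stream(9))
    s <- layout_scheme(steps, "single_line", d, rng_stream(10))
    f <- tempfile(fileext = ".png")
    r <- render_scheme(s, f)
    expect_true(file.exists(f))
    expect_identical(nrow(validate_scheme(r$scheme)), 0L)
  }
})

test_that("a molecule wider than the wrap threshold is a hard layout error", {
  style <- style_config(canvas_max_width = 120,
                        molecule_scale_range = c(30, 30))
  steps <- list(list(reactants = "CCCCCCCCCCCC", agents = character(0),
                     products = "C", conditions = list()))
  expect_error(layout_scheme(steps, "single_line", style, rng_stream(1)),
               "wider than canvas_max_width")
})
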