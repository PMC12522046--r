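# Dataset builder: split law, annotation round trips, batch build.

test_that("split sizes follow the rounding rule", {
  sp <- split_dataset(sprintf("x%04d", 1:1000), c(8, 1, 1), rng_stream(4))
  expect_identical(as.vector(table(factor(sp$split,
                                          c("train", "val", "test")))),
                   c(800L, 100L, 100L))
  sp7 <- split_dataset(letters[1:7], c(8, 1, 1), rng_stream(4))
  expect_identical(as.vector(table(factor(sp7$split,
                                          c("train", "val", "test")))),
                   c(6L, 1L, 0L))
  sp10 <- split_dataset(letters[1:10], c(1, 0, 0), rng_stream(4))
  expect_true(all(sp10$split == "train"))
})

test_that("splits are disjoint, exhaustive and stable under the seed", {
  ids <- sprintf("id%03d", 1:137)
  a <- split_dataset(ids, c(8, 1, 1), rng_stream(12))
  b <- split_dataset(ids, c(8, 1, 1), rng_stream(12))
  c <- split_dataset(ids, c(8, 1, 1), rng_stream(13))
  expect_identical(a, b)
  expect_false(identical(a$split, c$split))
  expect_setequal(a$id, ids)
  expect_true(all(a$split %in% c("train", "val", "test")))
})

test_that("three non-empty splits need at least three records", {
  expect_error(split_dataset(c("a", "b"), c(8, 1, 1), rng_stream(1)),
               "at least 3")
})

test_that("annotation records round-trip through JSON without loss", {
  s <- gen_scheme(7)
  rec <- scheme_to_record(s, "images/img_00001.png", c(1L, 7L))
  f <- tempfile(fileext = ".json")
  write_annotation(rec, f)
  back <- read_annotation(f)
  expect_equal(unclass(back), unclass(rec), tolerance = 1e-12)
  # and the scheme rebuilt from it is structurally identical
  s2 <- record_to_scheme(back)
  expect_identical(nrow(validate_scheme(s2)), 0L)
  expect_identical(length(s2$components), length(s$components))
})

test_that("schema violations are reported with their JSON path", {
  s <- gen_scheme(7)
  rec <- unclass(scheme_to_record(s))
  f <- tempfile(fileext = ".json")
  rec_nosteps <- rec; rec_nosteps$steps <- NULL
  jsonlite::write_json(rec_nosteps, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_annotation(f), "\\$\\.steps")
  rec_badrole <- rec
  rec_badrole$components[[1]]$role <- "catalyst"
  jsonlite::write_json(rec_badrole, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_annotation(f), "role")
})

test_that("build_dataset writes n images + annotations and a manifest", {
  out <- file.path(tempdir(), "ds_small")
  unlink(out, recursive = TRUE)
  m <- build_dataset(4, out, seed = 21)
  expect_identical(nrow(m$records), 4L)
  expect_true(all(file.exists(file.path(out, m$records$image_path))))
  expect_true(all(file.exists(file.path(out, m$records$annotation_path))))
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  schemes <- load_schemes(m)
  for (s in schemes) expect_identical(nrow(validate_scheme(s)), 0L)
})

test_that("every annotation's assembled reaction equals its source reaction", {
  out <- file.path(tempdir(), "ds_src")
  unlink(out, recursive = TRUE)
  m <- build_dataset(5, out, seed = 33)
  for (i in seq_len(nrow(m$records))) {
    rec <- read_annotation(file.path(out, m$records$annotation_path[i]))
    for (st in rec$steps) {
      expect_true(reaction_equal(st$reaction_smiles, st$source_smiles,
                                 include_agents = FALSE))
      expect_true(reaction_equal(st$reaction_smiles, st$source_smiles,
                                 include_agents = TRUE))
    }
  }
})

test_that("rebuilding with the same seed is byte-identical", {
  out1 <- file.path(tempdir(), "ds_a"); out2 <- file.path(tempdir(), "ds_b")
  unlink(c(out1, out2), recursive = TRUE)
  m1 <- build_dataset(3, out1, seed = 77)
  m2 <- build_dataset(3, out2, seed = 77)
  for (i in 1:3) {
    a <- readLines(file.path(out1, m1$records$annotation_path[i]), warn = FALSE)
    b <- readLines(file.path(out2, m2$records$annotation_path[i]), warn = FALSE)
    expect_identical(a, b)
  }
})

test_that("an unparseable source reaction is resampled and logged", {
  src <- reaction_source_file(c("CCO>>CC=O", "CC=O>>CC(=O)O",
                                "this-is-not-smiles>>C", "CCCO>>CCC=O",
                                "CCBr.N>>CCN"))
  out <- file.path(tempdir(), "ds_bad")
  unlink(out, recursive = TRUE)
  style <- style_config(pattern_weights = c(single_line = 1,
                                            multiple_line = 0,
                                            branch = 0, cycle = 0))
  m <- build_dataset(6, out, source = src, style = style, seed = 3)
  expect_identical(nrow(m$records), 6L)
  expect_gte(length(m$resample_events), 1)
})

test_that("a file source cannot produce cycle layouts", {
  src <- reaction_source_file(toy_reactions())
  expect_false("cycle" %in% supported_patterns(src))
  expect_error(sample_steps(src, "cycle", 3, rng_stream(1)), "cycle")
})

test_that("the COCO export covers every component of every image", {
  out <- file.path(tempdir(), "ds_coco")
  unlink(out, recursive = TRUE)
  m <- build_dataset(3, out, seed = 9)
  f <- file.path(out, "coco.json")
  coco_export(m, f)
  coco <- jsonlite::read_json(f)
  expect_length(coco$images, 3)
  n_comp <- sum(vapply(seq_len(3), function(i) {
    rec <- read_annotation(file.path(out, m$records$annotation_path[i]))
    length(rec$components)
  }, 0))
  expect_length(coco$annotations, n_comp)
  expect_identical(vapply(coco$categories, `[[`, "", "name"),
                   c("reactant", "condition", "product"))
})
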