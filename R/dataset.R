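# Dataset construction: batch generation of images + annotation JSON,
# train/val/test splitting, manifest I/O and a COCO-style export for
# detection-only consumers. One JSON document per image is the canonical
# annotation form (a JSON-Schema description ships in inst/extdata).

#' Convert a scheme to an annotation record
#'
#' @param scheme A (rendered) [reaction_scheme()].
#' @param image_path Path of the rendered image, as stored in the record.
#' @param seed Integer vector identifying the generation substream.
#' @return A list of class `rxn_annotation`.
#' @export
scheme_to_record <- function(scheme, image_path = NA_character_,
                             seed = integer(0)) {
  box4 <- function(b) c(b$x_min, b$y_min, b$x_max, b$y_max)
  comps <- lapply(scheme$components, function(cmp) {
    out <- list(id = as.character(cmp$id), role = cmp$role,
                bbox = box4(cmp$bbox))
    if (identical(cmp$role, "condition")) {
      out$items <- lapply(cmp$items, function(it)
        list(text = it$text, role = it$role,
             bbox = if (is.null(it$bbox)) NULL else box4(it$bbox)))
    } else out$smiles <- cmp$smiles
    out
  })
  steps <- lapply(scheme$steps, function(st) {
    a <- st$arrow
    list(reactant_ids = as.list(st$reactant_ids),
         condition_ids = as.list(st$condition_ids),
         product_ids = as.list(st$product_ids),
         arrow = c(list(start = a$start, end = a$end, kind = a$kind,
                        crossed_out = a$crossed_out),
                   if (!is.null(a$control)) list(control = a$control)),
         reaction_smiles = assemble_reaction_smiles(st, scheme),
         source_smiles = st$source_smiles %||% NULL)
  })
  structure(list(image_path = image_path,
                 canvas = list(width = scheme$canvas_width,
                               height = scheme$canvas_height),
                 pattern = scheme$pattern,
                 seed = as.integer(seed),
                 components = comps, steps = steps),
            class = "rxn_annotation")
}

#' Rebuild a scheme from an annotation record
#'
#' @param record An `rxn_annotation` (see [read_annotation()]).
#' @return An [reaction_scheme()].
#' @export
record_to_scheme <- function(record) {
  unbox4 <- function(b) bbox(b[[1]], b[[2]], b[[3]], b[[4]])
  comps <- lapply(record$components, function(cmp) {
    if (identical(cmp$role, "condition")) {
      items <- lapply(cmp$items, function(it)
        condition_item(it$text, it$role,
                       if (is.null(it$bbox)) NULL else unbox4(it$bbox)))
      component(cmp$id, cmp$role, unbox4(cmp$bbox), items = items)
    } else component(cmp$id, cmp$role, unbox4(cmp$bbox), smiles = cmp$smiles)
  })
  steps <- lapply(record$steps, function(st) {
    a <- st$arrow
    ctrl <- if (is.null(a$control) || !length(a$control)) NULL
    else lapply(a$control, unlist)
    s <- reaction_step(unlist(st$reactant_ids),
                       unlist(st$condition_ids) %||% character(0),
                       unlist(st$product_ids),
                       arrow(unlist(a$start), unlist(a$end), a$kind,
                             isTRUE(a$crossed_out), ctrl))
    s$source_smiles <- st$source_smiles %||% NULL
    s
  })
  reaction_scheme(record$canvas$width, record$canvas$height, comps, steps,
                  record$pattern)
}

# structural validation with JSON-path error messages
check_annotation <- function(x, path = "$") {
  fail <- function(p, why) stop("annotation schema violation at ", p, ": ",
                                why, call. = FALSE)
  need <- function(field) {
    if (is.null(x[[field]])) fail(paste0(path, ".", field), "missing")
    x[[field]]
  }
  canvas <- need("canvas")
  if (is.null(canvas$width) || is.null(canvas$height))
    fail(paste0(path, ".canvas"), "needs width and height")
  pat <- need("pattern")
  if (!pat %in% SCHEME_PATTERNS)
    fail(paste0(path, ".pattern"), paste("not a layout pattern:", pat))
  comps <- need("components")
  for (i in seq_along(comps)) {
    cp <- paste0(path, ".components[", i, "]")
    cmp <- comps[[i]]
    if (is.null(cmp$id)) fail(paste0(cp, ".id"), "missing")
    if (is.null(cmp$role) ||
        !cmp$role %in% c("reactant", "condition", "product"))
      fail(paste0(cp, ".role"),
           paste("not a component role:", cmp$role %||% "<missing>"))
    if (is.null(cmp$bbox) || length(unlist(cmp$bbox)) != 4)
      fail(paste0(cp, ".bbox"), "needs 4 numbers")
    if (identical(cmp$role, "condition")) {
      if (is.null(cmp$items)) fail(paste0(cp, ".items"), "missing")
      for (j in seq_along(cmp$items)) {
        it <- cmp$items[[j]]
        ip <- paste0(cp, ".items[", j, "]")
        if (is.null(it$text)) fail(paste0(ip, ".text"), "missing")
        if (is.null(it$role) || !it$role %in% CONDITION_ROLES)
          fail(paste0(ip, ".role"),
               paste("not a condition role:", it$role %||% "<missing>"))
      }
    } else if (is.null(cmp$smiles)) fail(paste0(cp, ".smiles"), "missing")
  }
  steps <- need("steps")
  ids <- vapply(comps, function(cmp) as.character(cmp$id), character(1))
  for (i in seq_along(steps)) {
    sp <- paste0(path, ".steps[", i, "]")
    st <- steps[[i]]
    for (f in c("reactant_ids", "product_ids"))
      if (is.null(st[[f]]) || !length(unlist(st[[f]])))
        fail(paste0(sp, ".", f), "needs >= 1 id")
    refs <- unlist(c(st$reactant_ids, st$condition_ids, st$product_ids))
    miss <- setdiff(refs, ids)
    if (length(miss))
      fail(paste0(sp), paste("unresolved component ids:",
                             paste(miss, collapse = ", ")))
    if (is.null(st$arrow) || is.null(st$arrow$start) ||
        is.null(st$arrow$end))
      fail(paste0(sp, ".arrow"), "needs start and end")
  }
  invisible(TRUE)
}

#' Write / read one annotation record
#'
#' `read_annotation(write_annotation(x, f))` reproduces `x` field for field;
#' files violating the schema raise an error naming the JSON path.
#'
#' @param record An `rxn_annotation`.
#' @param path File path for the JSON document.
#' @return `write_annotation` the path invisibly; `read_annotation` the
#'   record.
#' @export
write_annotation <- function(record, path) {
  check_annotation(unclass(record))
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_annotation(x)
  x$seed <- as.integer(unlist(x$seed))
  x$components <- lapply(x$components, function(cmp) {
    cmp$bbox <- as.numeric(unlist(cmp$bbox))
    if (!is.null(cmp$items))
      cmp$items <- lapply(cmp$items, function(it) {
        if (!is.null(it$bbox)) it$bbox <- as.numeric(unlist(it$bbox))
        it
      })
    cmp
  })
  x$steps <- lapply(x$steps, function(st) {
    st$arrow$start <- as.numeric(unlist(st$arrow$start))
    st$arrow$end <- as.numeric(unlist(st$arrow$end))
    if (!is.null(st$arrow$control) && length(st$arrow$control))
      st$arrow$control <- lapply(st$arrow$control,
                                 function(p) as.numeric(unlist(p)))
    else st$arrow$control <- NULL
    st
  })
  structure(x, class = "rxn_annotation")
}

#' Assign train/val/test splits
#'
#' Sizes follow the stated rounding rule: `|train| = round(N * r1/S)`,
#' `|val| = round(N * r2/S)` (round half up), and the remainder goes to test.
#' Assignment is a seed-deterministic shuffle.
#'
#' @param ids Vector of record ids.
#' @param ratios Positive ratios `c(train, val, test)`, e.g. `c(8, 1, 1)`.
#' @param rng An [rng_stream()].
#' @return A data frame with columns `id` and `split`.
#' @export
split_dataset <- function(ids, ratios = c(8, 1, 1), rng = rng_stream(1)) {
  stopifnot(length(ratios) == 3, all(ratios >= 0), sum(ratios) > 0)
  N <- length(ids)
  if (N < 3 && all(ratios > 0))
    stop("need at least 3 records for three non-empty splits")
  S <- sum(ratios)
  rh <- function(x) floor(x + 0.5)
  n_train <- rh(N * ratios[1] / S)
  n_val <- rh(N * ratios[2] / S)
  if (n_train + n_val > N) n_val <- N - n_train
  n_test <- N - n_train - n_val
  perm <- with_rng(rng, sample.int(N))
  split <- character(N)
  split[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) split[perm[n_train + seq_len(n_val)]] <- "val"
  if (n_test > 0) split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  data.frame(id = ids, split = split, stringsAsFactors = FALSE)
}

.steps_for_pattern <- function(pattern, rng) {
  with_rng(rng, switch(pattern,
                       single_line = 1L,
                       multiple_line = sample(2:3, 1),
                       branch = sample(2:3, 1),
                       cycle = sample(3:4, 1)))
}

#' Build a synthetic reaction-image dataset
#'
#' Generates `n` annotated images: per image one style draw, abstract steps
#' from the reaction source for the drawn pattern, sampled condition text,
#' layout, rendering and annotation. Items that fail (unparseable source
#' reaction, layout overflow, depiction failure) are logged and resampled.
#' Rebuilding with the same seed reproduces the annotations byte for byte.
#'
#' @param n Number of images (>= 1).
#' @param out_dir Output directory (created; gains `images/`, `annotations/`,
#'   `manifest.tsv`).
#' @param source A reaction source ([toy_reaction_source()] or
#'   [reaction_source_file()]).
#' @param style An [style_config()].
#' @param cond An [condition_spec()].
#' @param seed Integer root seed.
#' @param ratios Split ratios passed to [split_dataset()].
#' @return An object of class `rxn_manifest`: a list with `records` (data
#'   frame id/image_path/annotation_path/split/pattern), `ratios`,
#'   `root_seed`, `resample_events`.
#' @export
build_dataset <- function(n, out_dir, source = toy_reaction_source(),
                          style = style_config(), cond = condition_spec(),
                          seed = style$seed %||% 1L, ratios = c(8, 1, 1)) {
  stopifnot(n >= 1)
  validate_style_config(style)
  validate_condition_spec(cond)
  pats <- supported_patterns(source)
  w <- style$pattern_weights[names(style$pattern_weights) %in% pats]
  if (!length(w) || sum(w) <= 0)
    stop("reaction source supports none of the configured patterns")
  w <- w / sum(w)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  root <- rng_stream(seed)
  resample_events <- list()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img_rel <- file.path("images", sprintf("img_%05d.png", i))
    ann_rel <- file.path("annotations", sprintf("ann_%05d.json", i))
    rec <- NULL
    for (attempt in 1:25) {
      rng_i <- rng_fork(rng_fork(root, i), attempt)
      res <- tryCatch({
        pattern <- with_rng(rng_fork(rng_i, 1), sample(names(w), 1, prob = w))
        k <- .steps_for_pattern(pattern, rng_fork(rng_i, 2))
        steps <- sample_steps(source, pattern, k, rng_fork(rng_i, 3))
        steps <- lapply(seq_along(steps), function(j) {
          st <- steps[[j]]
          spec_j <- cond
          if (length(st$agents) || length(st$agent_names))
            spec_j$p_role_present[["agent"]] <- 0
          items <- lapply(st$agent_names %||% character(0),
                          function(a) condition_item(a, "agent"))
          st$conditions <- c(items,
                             sample_conditions(rng_fork(rng_i, 10 + j),
                                               spec_j))
          st
        })
        draw <- draw_style(style, rng_fork(rng_i, 4))
        draw$pattern <- pattern
        scheme <- layout_scheme(steps, pattern, draw, rng_i)
        rendered <- render_scheme(scheme, file.path(out_dir, img_rel))
        scheme_to_record(rendered$scheme, img_rel,
                         c(root$root_seed, i, attempt))
      }, error = function(e) e)
      if (!inherits(res, "error")) { rec <- res; break }
      resample_events[[length(resample_events) + 1]] <-
        list(image = i, attempt = attempt, message = conditionMessage(res))
    }
    if (is.null(rec))
      stop("could not generate image ", i, " after 25 attempts; last error: ",
           resample_events[[length(resample_events)]]$message)
    write_annotation(rec, file.path(out_dir, ann_rel))
    rows[[i]] <- data.frame(id = sprintf("img_%05d", i), image_path = img_rel,
                            annotation_path = ann_rel, pattern = rec$pattern,
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  sp <- split_dataset(records$id, ratios, rng_fork(root, 0L))
  records$split <- sp$split[match(records$id, sp$id)]
  manifest <- structure(list(records = records, ratios = ratios,
                             root_seed = as.integer(seed),
                             resample_events = resample_events,
                             out_dir = out_dir),
                        class = "rxn_manifest")
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

#' Write / read a dataset manifest
#'
#' @param manifest An `rxn_manifest`.
#' @param path TSV path.
#' @return `write_manifest` the path invisibly; `read_manifest` the manifest.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest$records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param root_seed,ratios Metadata not stored in the TSV.
#' @export
read_manifest <- function(path, root_seed = NA_integer_,
                          ratios = c(8, 1, 1)) {
  records <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  structure(list(records = records, ratios = ratios, root_seed = root_seed,
                 resample_events = list(), out_dir = dirname(path)),
            class = "rxn_manifest")
}

#' Load the ground-truth schemes of a manifest
#'
#' @param manifest An `rxn_manifest`.
#' @return Named list of schemes (by record id), each with the annotation
#'   record attached as attribute `record`.
#' @export
load_schemes <- function(manifest) {
  out <- lapply(seq_len(nrow(manifest$records)), function(i) {
    rec <- read_annotation(file.path(manifest$out_dir,
                                     manifest$records$annotation_path[i]))
    s <- record_to_scheme(rec)
    attr(s, "record") <- rec
    s
  })
  names(out) <- manifest$records$id
  out
}

#' COCO-style detection export
#'
#' Writes a single COCO JSON (images, annotations with `[x, y, w, h]` boxes,
#' categories reactant/condition/product) for detection-only consumers.
#'
#' @param manifest An `rxn_manifest`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
coco_export <- function(manifest, path) {
  cats <- list(list(id = 1, name = "reactant"),
               list(id = 2, name = "condition"),
               list(id = 3, name = "product"))
  cat_id <- c(reactant = 1, condition = 2, product = 3)
  images <- list(); annotations <- list(); aid <- 0
  for (i in seq_len(nrow(manifest$records))) {
    rec <- read_annotation(file.path(manifest$out_dir,
                                     manifest$records$annotation_path[i]))
    images[[i]] <- list(id = i, file_name = rec$image_path,
                        width = rec$canvas$width, height = rec$canvas$height)
    for (cmp in rec$components) {
      aid <- aid + 1
      b <- cmp$bbox
      annotations[[aid]] <- list(
        id = aid, image_id = i, category_id = unname(cat_id[[cmp$role]]),
        bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
        area = (b[3] - b[1]) * (b[4] - b[2]), iscrowd = 0)
    }
  }
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
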