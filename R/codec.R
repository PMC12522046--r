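# Token-sequence annotation codec. A scheme is linearized into one block per
# reaction step delimited by paired start-end tokens; inside a step, each
# component becomes its own paired block carrying 4 quantized coordinate
# tokens; condition blocks additionally carry role token + text per item,
# with role "other" items carrying text but no role token. The decoder is
# total: malformed input yields a best-effort scheme plus diagnostics.

.STRUCT_TOKENS <- c(RXN_START = "RXN_START", RXN_END = "RXN_END",
                    RCT_START = "RCT_START", RCT_END = "RCT_END",
                    CND_START = "CND_START", CND_END = "CND_END",
                    PRD_START = "PRD_START", PRD_END = "PRD_END")
.ROLE_TOKENS <- c(agent = "[Age]", solvent = "[Sol]", temperature = "[Tem]",
                  time = "[Time]", yield = "[Yld]")

#' Token vocabulary
#'
#' @param n_bins Number of coordinate bins per axis (>= 2).
#' @return List with `structural`, `roles`, `n_bins`.
#' @export
rxn_vocabulary <- function(n_bins = 1000) {
  stopifnot(n_bins >= 2)
  list(structural = unname(.STRUCT_TOKENS), roles = unname(.ROLE_TOKENS),
       n_bins = as.integer(n_bins))
}

#' Quantize / dequantize a box into coordinate tokens
#'
#' Each coordinate `c` maps to `round(c / extent * (B - 1))` clamped to
#' `[0, B - 1]`; dequantization inverts with absolute error at most
#' `extent / (2 * (B - 1))` per coordinate.
#'
#' @param b An [bbox()] inside the canvas.
#' @param canvas_width,canvas_height Canvas extent in pixels.
#' @param n_bins Bins per axis (>= 2).
#' @return `quantize_bbox`: integer vector `(x_min, y_min, x_max, y_max)` in
#'   `0 .. n_bins - 1`; `dequantize_bbox`: an [bbox()].
#' @export
quantize_bbox <- function(b, canvas_width, canvas_height, n_bins = 1000) {
  stopifnot(n_bins >= 2)
  if (b$x_min < 0 || b$y_min < 0 || b$x_max > canvas_width + 1e-6 ||
      b$y_max > canvas_height + 1e-6)
    stop("bbox outside canvas")
  q <- function(c, extent) {
    v <- floor(c / extent * (n_bins - 1) + 0.5)
    as.integer(min(max(v, 0), n_bins - 1))
  }
  c(q(b$x_min, canvas_width), q(b$y_min, canvas_height),
    q(b$x_max, canvas_width), q(b$y_max, canvas_height))
}

#' @rdname quantize_bbox
#' @param q Integer vector of 4 coordinate tokens.
#' @export
dequantize_bbox <- function(q, canvas_width, canvas_height, n_bins = 1000) {
  d <- function(v, extent) v / (n_bins - 1) * extent
  bbox(d(q[1], canvas_width), d(q[2], canvas_height),
       d(q[3], canvas_width), d(q[4], canvas_height))
}

# text payloads travel as single tokens: escape backslash, space and a
# leading bracket so they cannot collide with vocabulary tokens
.escape_text <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub(" ", "\\s", s, fixed = TRUE)
  if (grepl("^\\[", s)) s <- paste0("\\", s)
  s
}
.unescape_text <- function(s) {
  out <- character(1)
  chars <- strsplit(s, "")[[1]]
  res <- c(); i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "\\" && i < length(chars)) {
      nxt <- chars[i + 1]
      res <- c(res, if (nxt == "s") " " else nxt)
      i <- i + 2
    } else { res <- c(res, chars[i]); i <- i + 1 }
  }
  paste(res, collapse = "")
}

# deterministic step order for the sequence: reading order (arrow midpoint,
# top-to-bottom then left-to-right) for line/branch patterns; for cycles the
# arrow chain starting from the step that leaves the topmost component
.step_order <- function(scheme) {
  n <- length(scheme$steps)
  if (n <= 1) return(seq_len(n))
  if (identical(scheme$pattern, "cycle")) {
    tops <- vapply(scheme$steps, function(st) {
      cmp <- scheme_component(scheme, st$reactant_ids[1])
      bbox_center(cmp$bbox)[2]
    }, 0)
    first <- which.min(tops)
    ord <- first
    while (length(ord) < n) {
      cur <- scheme$steps[[ord[length(ord)]]]
      nxt <- which(vapply(scheme$steps, function(st)
        any(st$reactant_ids %in% cur$product_ids), logical(1)))
      nxt <- setdiff(nxt, ord)
      if (!length(nxt)) { ord <- c(ord, setdiff(seq_len(n), ord)); break }
      ord <- c(ord, nxt[1])
    }
    return(ord)
  }
  mids <- t(vapply(scheme$steps, function(st)
    (st$arrow$start + st$arrow$end) / 2, numeric(2)))
  order(round(mids[, 2] / 8), mids[, 1])
}

#' Encode a scheme as a token sequence
#'
#' One `RXN_START ... RXN_END` block per step; inside, component blocks in
#' the order reactants, conditions, products, each holding its 4 quantized
#' coordinates; condition blocks carry `role-token text` per item (no role
#' token for role "other").
#'
#' @param scheme A valid [reaction_scheme()].
#' @param n_bins Coordinate bins per axis.
#' @return Character vector of tokens with class `rxn_tokens` and attributes
#'   `n_bins`, `canvas_width`, `canvas_height`.
#' @export
encode_scheme <- function(scheme, n_bins = 1000) {
  W <- scheme$canvas_width; H <- scheme$canvas_height
  toks <- character(0)
  emit <- function(...) toks <<- c(toks, as.character(c(...)))
  comp_block <- function(id, start, end) {
    cmp <- scheme_component(scheme, id)
    q <- quantize_bbox(cmp$bbox, W, H, n_bins)
    emit(start, q)
    if (identical(cmp$role, "condition")) {
      for (it in cmp$items) {
        if (!identical(it$role, "other")) emit(.ROLE_TOKENS[[it$role]])
        emit(.escape_text(it$text))
      }
    }
    emit(end)
  }
  for (k in .step_order(scheme)) {
    st <- scheme$steps[[k]]
    emit("RXN_START")
    for (id in st$reactant_ids) comp_block(id, "RCT_START", "RCT_END")
    for (id in st$condition_ids) comp_block(id, "CND_START", "CND_END")
    for (id in st$product_ids) comp_block(id, "PRD_START", "PRD_END")
    emit("RXN_END")
  }
  structure(toks, class = "rxn_tokens", n_bins = as.integer(n_bins),
            canvas_width = W, canvas_height = H)
}

#' Decode a token sequence into a scheme skeleton
#'
#' Total parser: well-formed input yields a scheme whose boxes equal the
#' originals within quantization error and whose roles and texts match
#' exactly; malformed input yields a best-effort partial scheme plus
#' diagnostics (never an error). Arrows are synthesized between reactant and
#' product boxes (the sequence does not carry arrow geometry).
#'
#' @param tokens Character vector of tokens (an `rxn_tokens` or plain).
#' @param canvas_width,canvas_height Canvas extent; defaults from attributes.
#' @param n_bins Bins per axis; default from attributes.
#' @return List with `scheme` (an [reaction_scheme()], possibly with no
#'   steps) and `diagnostics` (data frame `position`, `issue`).
#' @export
decode_tokens <- function(tokens,
                          canvas_width = attr(tokens, "canvas_width"),
                          canvas_height = attr(tokens, "canvas_height"),
                          n_bins = attr(tokens, "n_bins")) {
  W <- canvas_width %||% 1000; H <- canvas_height %||% 1000
  B <- n_bins %||% 1000
  toks <- as.character(tokens)
  diags <- list(); comps <- list(); steps <- list()
  note <- function(pos, issue)
    diags[[length(diags) + 1]] <<- data.frame(position = pos, issue = issue)
  n <- length(toks); i <- 1; cid <- 0
  starts <- c(RCT_START = "reactant", CND_START = "condition",
              PRD_START = "product")
  ends <- c(reactant = "RCT_END", condition = "CND_END", product = "PRD_END")
  role_of <- names(.ROLE_TOKENS); names(role_of) <- unname(.ROLE_TOKENS)
  if (!n) note(0, "empty token list")
  while (i <= n) {
    if (!identical(toks[i], "RXN_START")) {
      note(i, paste("unexpected token outside reaction block:", toks[i]))
      i <- i + 1; next
    }
    i <- i + 1
    r_ids <- c(); c_ids <- c(); p_ids <- c()
    closed <- FALSE
    while (i <= n) {
      tk <- toks[i]
      if (identical(tk, "RXN_END")) { closed <- TRUE; i <- i + 1; break }
      if (!tk %in% names(starts)) {
        if (identical(tk, "RXN_START")) { note(i, "unclosed reaction block")
          break }
        note(i, paste("unexpected token inside reaction block:", tk))
        i <- i + 1; next
      }
      role <- starts[[tk]]
      i <- i + 1
      q <- suppressWarnings(as.integer(toks[seq(i, length.out = 4)]))
      if (i + 3 > n || anyNA(q)) {
        note(i, "truncated component block (needs 4 coordinate tokens)")
        i <- min(i + 4, n + 1); next
      }
      q <- pmin(pmax(q, 0L), B - 1L)
      i <- i + 4
      if (q[1] >= q[3] || q[2] >= q[4]) {
        note(i, "degenerate coordinates, component dropped")
        # skip to the closing token if present
        while (i <= n && !toks[i] %in% c(ends[[role]], "RXN_END")) i <- i + 1
        if (i <= n && identical(toks[i], ends[[role]])) i <- i + 1
        next
      }
      items <- list(); pending_role <- NULL; ok <- FALSE
      while (i <= n) {
        tk2 <- toks[i]
        if (identical(tk2, ends[[role]])) { ok <- TRUE; i <- i + 1; break }
        if (tk2 %in% c("RXN_END", "RXN_START", names(starts))) break
        if (identical(role, "condition")) {
          if (tk2 %in% names(role_of)) {
            pending_role <- role_of[[tk2]]
          } else {
            items[[length(items) + 1]] <-
              condition_item(.unescape_text(tk2), pending_role %||% "other")
            pending_role <- NULL
          }
        } else note(i, paste("unexpected payload in molecule block:", tk2))
        i <- i + 1
      }
      if (!ok) { note(i, "unclosed component block, dropped"); next }
      if (identical(role, "condition") && !length(items)) {
        note(i, "condition block without items, dropped"); next
      }
      cid <- cid + 1
      id <- sprintf("d%02d", cid)
      comps[[id]] <- component(
        id, role, dequantize_bbox(q, W, H, B),
        smiles = if (role != "condition") "*" else NULL,
        items = if (role == "condition") items else NULL)
      if (role == "reactant") r_ids <- c(r_ids, id)
      else if (role == "condition") c_ids <- c(c_ids, id)
      else p_ids <- c(p_ids, id)
    }
    if (!closed) note(i, "reaction block not closed by RXN_END")
    if (length(r_ids) && length(p_ids)) {
      a <- arrow(bbox_center(comps[[r_ids[1]]]$bbox),
                 bbox_center(comps[[p_ids[1]]]$bbox), "straight")
      if (all(a$start == a$end)) a$end <- a$end + c(1, 0)
      steps[[length(steps) + 1]] <- reaction_step(r_ids, c_ids, p_ids, a)
    } else if (length(r_ids) || length(c_ids) || length(p_ids)) {
      note(i, "incomplete reaction (missing reactants or products), dropped")
      for (id in c(r_ids, c_ids, p_ids)) comps[[id]] <- NULL
    }
  }
  kept <- unique(unlist(lapply(steps, function(s)
    c(s$reactant_ids, s$condition_ids, s$product_ids))))
  comps <- comps[names(comps) %in% kept]
  scheme <- reaction_scheme(W, H, unname(comps), steps, "single_line")
  diagnostics <- if (length(diags)) do.call(rbind, diags)
  else data.frame(position = integer(0), issue = character(0))
  list(scheme = scheme, diagnostics = diagnostics)
}

#' Write / read token streams
#'
#' Plain-text form: one space-separated token sequence per line; a JSON array
#' form and the vocabulary are written alongside (`.json`, `.vocab.json`).
#'
#' @param token_list List of `rxn_tokens`.
#' @param path Output path for the plain-text stream.
#' @return `write_tokens` the path invisibly; `read_tokens` a list of token
#'   vectors (attributes restored from the JSON sidecar when present).
#' @export
write_tokens <- function(token_list, path) {
  lines <- vapply(token_list, paste, character(1), collapse = " ")
  writeLines(lines, path)
  meta <- lapply(token_list, function(t)
    list(tokens = as.character(t), n_bins = attr(t, "n_bins"),
         canvas_width = attr(t, "canvas_width"),
         canvas_height = attr(t, "canvas_height")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(rxn_vocabulary(attr(token_list[[1]], "n_bins") %||%
                                        1000),
                       paste0(path, ".vocab.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tokens
#' @export
read_tokens <- function(path) {
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
    lapply(meta, function(m)
      structure(vapply(m$tokens, as.character, character(1),
                       USE.NAMES = FALSE),
                class = "rxn_tokens", n_bins = m$n_bins,
                canvas_width = m$canvas_width,
                canvas_height = m$canvas_height))
  } else {
    lapply(readLines(path, warn = FALSE),
           function(l) strsplit(l, " ", fixed = TRUE)[[1]])
  }
}
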