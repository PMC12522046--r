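# Rasterization. Schemes are drawn onto an 8-bit RGB PNG with base graphics
# in pixel coordinates (origin top-left, y growing downward). After drawing,
# the raster is read back and every component/item box is tightened to the
# ink actually drawn inside its allocated region, so ground-truth boxes are
# pixel-accurate regardless of font metrics.

.DEV_POINTSIZE <- 12

.open_canvas <- function(file, W, H) {
  grDevices::png(file, width = W, height = H, res = 72,
                 pointsize = .DEV_POINTSIZE, type = "cairo", antialias = "gray")
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, W), ylim = c(H, 0))
  graphics::rect(-1, -1, W + 1, H + 1, col = "white", border = NA)
}

.cex <- function(px) px / .DEV_POINTSIZE

# atoms drawn as element labels when not plain carbon; bonds are trimmed
# around labelled atoms so text stays readable
.draw_molecule <- function(cmp, scale, lwd) {
  g <- mol_geometry(cmp$smiles)
  b <- cmp$bbox
  cx <- (b$x_min + b$x_max) / 2; cy <- (b$y_min + b$y_max) / 2
  mx <- if (length(g$x)) mean(range(g$x)) else 0
  my <- if (length(g$y)) mean(range(g$y)) else 0
  X <- cx + (g$x - mx) * scale
  Y <- cy - (g$y - my) * scale          # chemistry y-up -> screen y-down
  labelled <- g$symbol != "C"
  deg <- tabulate(c(g$bonds$from, g$bonds$to), nbins = length(X))
  labelled <- labelled | deg == 0       # lone carbons still get a label
  lab_px <- max(9, 0.45 * scale)
  trim <- 0.30 * scale
  for (bi in seq_len(nrow(g$bonds))) {
    i <- g$bonds$from[bi]; j <- g$bonds$to[bi]
    p <- c(X[i], Y[i]); q <- c(X[j], Y[j])
    d <- q - p; len <- sqrt(sum(d^2)); if (len < 1e-9) next
    u <- d / len
    if (labelled[i]) p <- p + u * trim
    if (labelled[j]) q <- q - u * trim
    nrm <- c(-u[2], u[1])
    ord <- g$bonds$order[bi]
    offs <- switch(as.character(ord), "1" = 0, "2" = c(-1, 1) * 0.09 * scale,
                   "3" = c(-0.11, 0, 0.11) * scale, 0)
    for (o in offs) {
      pp <- p + nrm * o; qq <- q + nrm * o
      graphics::segments(pp[1], pp[2], qq[1], qq[2], lwd = lwd)
    }
  }
  for (i in which(labelled))
    graphics::text(X[i], Y[i], g$symbol[i], cex = .cex(lab_px), font = 1)
}

.draw_arrow_head <- function(tip, dir, size, lwd) {
  u <- dir / sqrt(sum(dir^2))
  nrm <- c(-u[2], u[1])
  a <- tip - u * size + nrm * size * 0.45
  b <- tip - u * size - nrm * size * 0.45
  graphics::polygon(c(a[1], tip[1], b[1]), c(a[2], tip[2], b[2]),
                    col = "black", border = NA)
}

.bezier_pts <- function(p0, pc, p1, n = 40) {
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * pc[1] + t^2 * p1[1]
  y <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * pc[2] + t^2 * p1[2]
  cbind(x, y)
}

.draw_arrow <- function(a, lwd) {
  hs <- 5 + 1.8 * lwd
  if (identical(a$kind, "curved")) {
    pts <- .bezier_pts(a$start, a$control[[1]], a$end)
    graphics::lines(pts[, 1], pts[, 2], lwd = lwd)
    m <- nrow(pts)
    .draw_arrow_head(a$end, pts[m, ] - pts[m - 1, ], hs, lwd)
  } else if (identical(a$kind, "bidirectional")) {
    d <- a$end - a$start; u <- d / sqrt(sum(d^2)); nrm <- c(-u[2], u[1])
    o <- nrm * 2.5
    graphics::segments(a$start[1] + o[1], a$start[2] + o[2],
                       a$end[1] + o[1], a$end[2] + o[2], lwd = lwd)
    graphics::segments(a$start[1] - o[1], a$start[2] - o[2],
                       a$end[1] - o[1], a$end[2] - o[2], lwd = lwd)
    .draw_arrow_head(a$end + o, d, hs, lwd)
    .draw_arrow_head(a$start - o, -d, hs, lwd)
  } else {
    graphics::segments(a$start[1], a$start[2], a$end[1], a$end[2], lwd = lwd)
    .draw_arrow_head(a$end, a$end - a$start, hs, lwd)
  }
  if (isTRUE(a$crossed_out)) {
    m <- (a$start + a$end) / 2
    s <- 9
    graphics::segments(m[1] - s, m[2] - s, m[1] + s, m[2] + s, lwd = lwd + 1)
    graphics::segments(m[1] - s, m[2] + s, m[1] + s, m[2] - s, lwd = lwd + 1)
  }
}

.draw_condition_items <- function(cmp, fs) {
  for (it in cmp$items) {
    ctr <- bbox_center(it$bbox)
    graphics::text(ctr[1], ctr[2], it$text, cex = .cex(fs),
                   srt = -(it$rotation %||% 0))
  }
}

# tight box of non-white ink inside a (padded) region of the raster;
# falls back to the allocated box when the region holds no ink
.tight_box <- function(img, b, W, H, pad = 2) {
  x0 <- max(1, floor(b$x_min) + 1 - pad); x1 <- min(W, ceiling(b$x_max) + pad)
  y0 <- max(1, floor(b$y_min) + 1 - pad); y1 <- min(H, ceiling(b$y_max) + pad)
  if (x1 < x0 || y1 < y0) return(b)
  sub <- img[y0:y1, x0:x1, 1:3, drop = FALSE]
  ink <- apply(sub < 0.985, c(1, 2), any)
  if (!any(ink)) return(b)
  rows <- which(apply(ink, 1, any)); cols <- which(apply(ink, 2, any))
  bbox(x0 + min(cols) - 2, y0 + min(rows) - 2,
       x0 + max(cols) - 1, y0 + max(rows) - 1)
}

#' Render a reaction scheme to a PNG image
#'
#' Draws molecule depictions, plus glyphs, arrows and condition text, then
#' reads the raster back and replaces every component and condition-item box
#' by the tight box of its drawn ink. Deterministic for a fixed scheme and
#' device configuration.
#'
#' @param scheme A laid-out [reaction_scheme()] (see [layout_scheme()]).
#' @param file Output PNG path.
#' @return Invisibly, a list with `file` and `scheme` (the finalized scheme
#'   with re-measured boxes).
#' @export
render_scheme <- function(scheme, file) {
  v <- validate_scheme(scheme)
  if (nrow(v))
    stop("refusing to render an invalid scheme: ",
         paste(unique(v$rule), collapse = "; "))
  draw <- scheme$style_draw %||% list(font_size = 12, line_width = 1.5,
                                      molecule_scale = 24)
  W <- scheme$canvas_width; H <- scheme$canvas_height
  .open_canvas(file, W, H)
  ok <- FALSE
  tryCatch({
    for (cmp in scheme$components) {
      if (identical(cmp$role, "condition"))
        .draw_condition_items(cmp, draw$font_size)
      else .draw_molecule(cmp, draw$molecule_scale, draw$line_width)
    }
    for (st in scheme$steps) .draw_arrow(st$arrow, draw$line_width)
    for (d in scheme$decorations %||% list()) {
      if (identical(d$type, "plus"))
        graphics::text(d$x, d$y, "+", cex = .cex(d$size))
      else if (identical(d$type, "comma"))
        graphics::text(d$x, d$y, ",", cex = .cex(d$size))
    }
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) stop("rendering failed for ", file)
  img <- png::readPNG(file)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  comps <- lapply(scheme$components, function(cmp) {
    if (identical(cmp$role, "condition")) {
      cmp$items <- lapply(cmp$items, function(it) {
        it$bbox <- .tight_box(img, it$bbox, W, H, pad = 1)
        it
      })
      xs <- unlist(lapply(cmp$items, function(it)
        c(it$bbox$x_min, it$bbox$x_max)))
      ys <- unlist(lapply(cmp$items, function(it)
        c(it$bbox$y_min, it$bbox$y_max)))
      cmp$bbox <- bbox(min(xs), min(ys), max(xs), max(ys))
    } else {
      cmp$bbox <- .tight_box(img, cmp$bbox, W, H, pad = 2)
    }
    cmp
  })
  out <- scheme
  out$components <- comps
  invisible(list(file = file, scheme = out))
}
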