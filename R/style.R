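# Augmentation axes: font size, line width, molecule depiction scale, layout
# pattern. A StyleConfig holds the ranges; draw_style samples one concrete
# draw per image.

#' Style / augmentation configuration
#'
#' @param font_size_range Condition/label font size range in points
#'   (at the raster's 72 ppi, 1 pt = 1 px).
#' @param line_width_range Bond and arrow line width range in pixels.
#' @param molecule_scale_range Pixels per molecule coordinate unit (one bond
#'   length is ~1 unit in the 2D coordinates).
#' @param pattern_weights Named probabilities over the four layout patterns;
#'   must sum to 1.
#' @param canvas_max_width Wrap threshold in pixels; content wider than this
#'   continues on the next line.
#' @param text_rotation_range Optional rotation range in degrees for condition
#'   text; `c(0, 0)` (the default) disables rotation.
#' @param seed Optional default root seed used by [build_dataset()].
#' @return An object of class `rxn_style_config`.
#' @export
style_config <- function(font_size_range = c(10, 16),
                         line_width_range = c(1, 3),
                         molecule_scale_range = c(20, 32),
                         pattern_weights = c(single_line = 0.25,
                                             multiple_line = 0.25,
                                             branch = 0.25, cycle = 0.25),
                         canvas_max_width = 1024,
                         text_rotation_range = c(0, 0),
                         seed = NULL) {
  style <- structure(
    list(font_size_range = as.numeric(font_size_range),
         line_width_range = as.numeric(line_width_range),
         molecule_scale_range = as.numeric(molecule_scale_range),
         pattern_weights = pattern_weights,
         canvas_max_width = as.numeric(canvas_max_width),
         text_rotation_range = as.numeric(text_rotation_range),
         seed = seed),
    class = "rxn_style_config")
  validate_style_config(style)
  style
}

validate_style_config <- function(style) {
  stopifnot(inherits(style, "rxn_style_config"))
  rng_ok <- function(r) length(r) == 2 && all(is.finite(r)) && r[1] <= r[2]
  if (!rng_ok(style$font_size_range)) stop("font_size_range must be (min, max)")
  if (!rng_ok(style$line_width_range))
    stop("line_width_range must be (min, max)")
  if (!rng_ok(style$molecule_scale_range))
    stop("molecule_scale_range must be (min, max)")
  w <- style$pattern_weights
  if (is.null(names(w)) || !all(names(w) %in% SCHEME_PATTERNS))
    stop("pattern_weights must be named by layout pattern")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("pattern_weights must be non-negative and sum to 1")
  if (style$canvas_max_width <= 0) stop("canvas_max_width must be positive")
  invisible(style)
}

#' Sample one concrete style draw
#'
#' Font size, line width and molecule scale are drawn uniformly from their
#' ranges; the layout pattern is drawn from `pattern_weights`.
#'
#' @param style An [style_config()].
#' @param rng An [rng_stream()].
#' @return A list with elements `font_size`, `line_width`, `molecule_scale`,
#'   `pattern`, `text_rotation`.
#' @export
draw_style <- function(style, rng) {
  validate_style_config(style)
  with_rng(rng, {
    u <- function(r) stats::runif(1, r[1], r[2])
    pat <- sample(names(style$pattern_weights), 1,
                  prob = style$pattern_weights)
    list(font_size = u(style$font_size_range),
         line_width = u(style$line_width_range),
         molecule_scale = u(style$molecule_scale_range),
         pattern = pat,
         text_rotation = u(style$text_rotation_range),
         canvas_max_width = style$canvas_max_width)
  })
}
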