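#' @title Color scales
#' @description
#' Three scale kinds cover the internal data representations: a piecewise
#' linear `gradient` for continuous values (green -> white -> red by
#' default for expression), an `ordered_palette` of threshold bands for
#' discrete ordered values (copy-number states), and a `category_palette`
#' for discrete unordered labels.
#' @name color_scales
NULL

hex_rgba <- function(col) {
  m <- grDevices::col2rgb(col, alpha = TRUE)
  sprintf("#%02X%02X%02X%02X", m[1L, ], m[2L, ], m[3L, ], m[4L, ])
}

#' Piecewise-linear gradient scale
#'
#' @param values strictly increasing anchor values.
#' @param colors one color per anchor (any R color spec).
#' @return a `color_scale` of kind `"gradient"`.
#' @export
gradient_scale <- function(values, colors) {
  if (length(values) < 2L || length(values) != length(colors)) {
    stopf("gradient needs >= 2 anchors with one color each")
  }
  if (any(diff(values) <= 0)) stopf("gradient anchors must be strictly increasing")
  structure(list(kind = "gradient", values = as.numeric(values),
                 rgba = grDevices::col2rgb(colors, alpha = TRUE)),
            class = "color_scale")
}

#' Ordered palette of threshold bands
#'
#' Band `i` covers values in `[lower[i], upper[i]]` (both inclusive);
#' bands must not overlap and must cover the integer range used.
#'
#' @param lower,upper band bounds (may be `-Inf` / `Inf`).
#' @param colors one color per band.
#' @return a `color_scale` of kind `"ordered_palette"`.
#' @export
ordered_palette <- function(lower, upper, colors) {
  if (length(lower) != length(upper) || length(lower) != length(colors)) {
    stopf("ordered palette needs equal-length lower, upper, colors")
  }
  if (any(lower > upper)) stopf("ordered palette bands need lower <= upper")
  o <- order(lower)
  if (any(utils::head(upper[o], -1L) >= lower[o][-1L])) {
    stopf("ordered palette bands overlap")
  }
  structure(list(kind = "ordered_palette", lower = as.numeric(lower),
                 upper = as.numeric(upper), colors = hex_rgba(colors)),
            class = "color_scale")
}

#' Category palette for unordered labels
#'
#' @param colors named vector, label -> color.
#' @return a `color_scale` of kind `"category_palette"`.
#' @export
category_palette <- function(colors) {
  if (is.null(names(colors)) || any(!nzchar(names(colors)))) {
    stopf("category palette colors must be named by label")
  }
  structure(list(kind = "category_palette",
                 colors = stats::setNames(hex_rgba(colors), names(colors))),
            class = "color_scale")
}

#' Default continuous expression scale
#'
#' Three anchors: data minimum -> green, midpoint -> white, maximum ->
#' red, matching the low-green / high-red convention for expression
#' staining. The midpoint defaults to the median of the mapped values,
#' which is robust to outliers; anchors are user-overridable by building
#' a [gradient_scale()] directly.
#'
#' @param values the numeric values the scale will color (NAs ignored).
#' @return a gradient `color_scale`.
#' @export
default_expression_scale <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) v <- c(0, 1)
  lo <- min(v); hi <- max(v)
  if (lo == hi) { lo <- lo - 1; hi <- hi + 1 }
  mid <- stats::median(v)
  if (mid <= lo || mid >= hi) mid <- (lo + hi) / 2
  gradient_scale(c(lo, mid, hi), c("#00FF00", "#FFFFFF", "#FF0000"))
}

#' Default discrete copy-number palette
#'
#' Blue marks gene loss (values of -1 and lower), yellow amplification
#' (values of +1 and higher), white the neutral state 0.
#'
#' @return an ordered-palette `color_scale`.
#' @export
default_copynumber_palette <- function() {
  ordered_palette(lower = c(-Inf, 0, 1), upper = c(-1, 0, Inf),
                  colors = c("#0000FF", "#FFFFFF", "#FFFF00"))
}

#' Default glyph style for mutated genes: a cyan triangle.
#'
#' @return `list(shape, color)`.
#' @export
default_mutation_glyph <- function() {
  list(shape = "triangle", color = "#00FFFF")
}

#' Map values (or labels) to colors through a scale
#'
#' Gradients interpolate linearly per channel between the bracketing
#' anchors and clamp outside the anchor range; ordered palettes look the
#' value up in their inclusive threshold bands; category palettes look
#' the label up exactly.
#'
#' @param scale a `color_scale`.
#' @param value numeric vector (gradient / ordered) or character vector
#'   (category).
#' @return character vector of `#RRGGBBAA` colors (`NA` in, `NA` out).
#' @export
value_to_color <- function(scale, value) {
  if (!inherits(scale, "color_scale")) stopf("not a color_scale")
  switch(scale$kind,
    gradient = {
      out <- rep(NA_character_, length(value))
      ok <- !is.na(value)
      if (any(ok)) {
        chans <- vapply(1:4, function(ch) {
          stats::approx(scale$values, scale$rgba[ch, ], xout = value[ok],
                        rule = 2)$y
        }, numeric(sum(ok)))
        chans <- matrix(round(chans), ncol = 4L)
        out[ok] <- sprintf("#%02X%02X%02X%02X",
                           chans[, 1L], chans[, 2L], chans[, 3L], chans[, 4L])
      }
      out
    },
    ordered_palette = {
      vapply(unname(value), function(v) {
        if (is.na(v)) return(NA_character_)
        band <- which(v >= scale$lower & v <= scale$upper)
        if (length(band) == 0L) {
          stopf("value %g falls in no band of the ordered palette", v)
        }
        scale$colors[band[1L]]
      }, "", USE.NAMES = FALSE)
    },
    category_palette = {
      vapply(unname(value), function(v) {
        if (is.na(v)) return(NA_character_)
        if (!v %in% names(scale$colors)) {
          stopf("unknown category label '%s'", v)
        }
        scale$colors[[v]]
      }, "", USE.NAMES = FALSE)
    },
    stopf("unknown scale kind '%s'", scale$kind)
  )
}
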