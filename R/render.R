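#' @title Rasterization and tile pyramids
#' @description
#' Levels are rendered slippy-map style: the world at zoom `z` is a
#' `256 * 2^z` pixel square of 256-px tiles, `4^z` tiles per level, origin
#' top-left. The map canvas sits in the top-left of the world at its
#' native pixel scale at `max_zoom` and is padded with a neutral
#' background. Every level is drawn at native resolution with that
#' level's visible entity set (semantic zoom) and then reduced by exact
#' block averaging, so stitching a level and halving it reproduces the
#' level above up to semantic content differences and 8-bit quantization.
#' @name color_render
NULL

TILE_SIZE <- 256L

# --- low-level raster helpers --------------------------------------------

# images are arrays [row (y), col (x), channel] with values in [0, 1]

new_canvas <- function(side, background = 0.93) {
  array(background, dim = c(side, side, 3L))
}

col_rgba01 <- function(col) {
  m <- grDevices::col2rgb(col, alpha = TRUE)[, 1L] / 255
  m
}

# Alpha-composite a flat color over the image on a logical pixel mask
# (mask given as row/col index matrix or logical matrix of image size).
blend_mask <- function(img, mask, col, alpha) {
  if (!any(mask)) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * col[ch]
    img[, , ch] <- plane
  }
  img
}

fill_rect <- function(img, x0, y0, x1, y1, col, alpha = 1) {
  side_y <- dim(img)[1L]; side_x <- dim(img)[2L]
  rows <- max(1L, ceiling(y0 + 0.5)):min(side_y, floor(y1 + 0.5))
  cols <- max(1L, ceiling(x0 + 0.5)):min(side_x, floor(x1 + 0.5))
  if (y1 < y0 || x1 < x0 || length(rows) == 0L || length(cols) == 0L ||
      rows[1L] > rows[length(rows)] || cols[1L] > cols[length(cols)]) {
    return(img)
  }
  for (ch in 1:3) {
    img[rows, cols, ch] <- (1 - alpha) * img[rows, cols, ch] + alpha * col[ch]
  }
  img
}

outline_rect <- function(img, x0, y0, x1, y1, col, lw = 1) {
  img <- fill_rect(img, x0, y0, x1, y0 + lw, col)
  img <- fill_rect(img, x0, y1 - lw, x1, y1, col)
  img <- fill_rect(img, x0, y0, x0 + lw, y1, col)
  fill_rect(img, x1 - lw, y0, x1, y1, col)
}

# Fill a convex shape given by vertices (in image pixel coordinates) by
# testing pixel centers within the shape's bounding box.
fill_convex <- function(img, verts, col, alpha = 1) {
  side_y <- dim(img)[1L]; side_x <- dim(img)[2L]
  rows <- max(1L, floor(min(verts[, 2L]))):min(side_y, ceiling(max(verts[, 2L])) + 1L)
  cols <- max(1L, floor(min(verts[, 1L]))):min(side_x, ceiling(max(verts[, 1L])) + 1L)
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  inside <- points_in_convex(verts, px, py)
  if (!any(inside)) return(img)
  idx <- cbind(rep(rows, times = length(cols))[inside],
               rep(cols, each = length(rows))[inside])
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- (1 - alpha) * plane[idx] + alpha * col[ch]
    img[, , ch] <- plane
  }
  img
}

shape_vertices <- function(shape, cx, cy, size) {
  s <- size / 2
  switch(shape,
    triangle = cbind(c(cx, cx - s, cx + s), c(cy - s, cy + s, cy + s)),
    square   = cbind(c(cx - s, cx + s, cx + s, cx - s),
                     c(cy - s, cy - s, cy + s, cy + s)),
    diamond  = cbind(c(cx, cx + s, cx, cx - s), c(cy - s, cy, cy + s, cy)),
    hexagon  = {
      a <- seq(0, 2 * pi, length.out = 7L)[-7L]
      cbind(cx + s * cos(a), cy + s * sin(a))
    },
    circle   = {  # polygonal approximation is fine at glyph sizes
      a <- seq(0, 2 * pi, length.out = 25L)[-25L]
      cbind(cx + s * cos(a), cy + s * sin(a))
    },
    stopf("unknown glyph shape '%s'", shape))
}

# Exact block-average downsampling by an integer factor.
downsample_mean <- function(img, factor) {
  if (factor == 1L) return(img)
  side <- dim(img)[1L]
  s2 <- side %/% factor
  dim(img) <- c(factor, s2, factor, s2, 3L)
  x <- colMeans(img, dims = 1L)            # (s2, factor, s2, 3)
  x <- aperm(x, c(2L, 1L, 3L, 4L))
  out <- colMeans(x, dims = 1L)            # (s2, s2, 3)
  out
}

# --- level rendering ------------------------------------------------------

world_side <- function(zoom) TILE_SIZE * 2L^as.integer(zoom)

# Scale from map pixels to native world pixels: native unless the canvas
# would overflow the max_zoom world square.
native_fit <- function(map) {
  min(1, world_side(map$max_zoom) / max(map$canvas_width, map$canvas_height))
}

#' Render one zoom level to a raster image
#'
#' Draws, in order: the staining territories, the map background and the
#' entities visible at this zoom (in black and white when staining is
#' active in `bw` mode, so territory colors are not polluted), then the
#' overlays of visible entities. Deterministic for fixed inputs.
#'
#' @param map a `network_map`.
#' @param zoom integer zoom level in `[0, max_zoom]`.
#' @param staining optional `staining_layer`.
#' @param overlays list of overlay objects (`marker`, `heatmap_overlay`,
#'   `barplot_overlay`, `glyph_overlay`).
#' @param background_mode `"bw"` or `"color"`; default follows the
#'   staining layer (`bw` when staining is present).
#' @return numeric array `[side, side, 3]`, values in `[0, 1]`, where
#'   `side = 256 * 2^zoom`.
#' @export
render_level <- function(map, zoom, staining = NULL, overlays = list(),
                         background_mode = NULL) {
  if (zoom < 0 || zoom > map$max_zoom) {
    stopf("zoom %s out of range [0, %d]", format(zoom), map$max_zoom)
  }
  background_mode <- background_mode %||%
    (if (!is.null(staining)) staining$background_mode else "bw")
  f <- native_fit(map)
  side <- world_side(map$max_zoom)
  img <- new_canvas(side)
  cw <- map$canvas_width * f
  ch <- map$canvas_height * f
  img <- fill_rect(img, 0, 0, cw, ch, c(1, 1, 1))

  if (!is.null(staining)) {
    img <- draw_staining(img, staining, f)
  }
  for (e in visible_entities(map, zoom)) {
    img <- draw_entity(img, e, f, background_mode)
  }
  vis_ids <- vapply(visible_entities(map, zoom), `[[`, "", "id")
  for (ov in overlays) {
    if (!is.null(ov$entity_id) && !ov$entity_id %in% vis_ids) next
    img <- draw_overlay(ov, img, f)
  }
  downsample_mean(img, 2L^(map$max_zoom - as.integer(zoom)))
}

# Rasterize staining by per-pixel nearest site (the exact Voronoi
# partition) restricted to each cell's extent square.
draw_staining <- function(img, staining, f) {
  cells <- staining$cells
  canvas <- attr(cells, "canvas")
  R <- attr(cells, "radius") %||% Inf
  nx <- max(1L, floor(canvas[["width"]] * f))
  ny <- max(1L, floor(canvas[["height"]] * f))
  # map coordinates of pixel centers
  mx <- ((seq_len(nx)) - 0.5) / f
  my <- ((seq_len(ny)) - 0.5) / f
  X <- matrix(mx, nrow = ny, ncol = nx, byrow = TRUE)
  Y <- matrix(my, nrow = ny, ncol = nx)
  best <- matrix(1L, ny, nx)
  sx <- vapply(cells, function(c) c$site[["x"]], 0)
  sy <- vapply(cells, function(c) c$site[["y"]], 0)
  bestd <- (X - sx[1L])^2 + (Y - sy[1L])^2
  for (i in seq_along(cells)[-1L]) {
    d <- (X - sx[i])^2 + (Y - sy[i])^2
    upd <- d < bestd
    bestd[upd] <- d[upd]
    best[upd] <- i
  }
  for (i in seq_along(cells)) {
    fillhex <- staining$fill[i]
    if (is.na(fillhex)) next  # unstained: neutral background shows through
    mine <- best == i & abs(X - sx[i]) <= R & abs(Y - sy[i]) <= R
    rgba <- col_rgba01(fillhex)
    img <- blend_submask(img, mine, rgba[1:3], rgba[4L] * staining$opacity,
                         ny, nx)
  }
  img
}

# blend a flat color over the top-left ny x nx window of img on a mask
blend_submask <- function(img, mask, col, alpha, ny, nx) {
  if (alpha == 0 || !any(mask)) return(img)
  for (ch in 1:3) {
    plane <- img[seq_len(ny), seq_len(nx), ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * col[ch]
    img[seq_len(ny), seq_len(nx), ch] <- plane
  }
  img
}

.class_colors <- c(
  protein = "#B3CDE3", gene = "#CCEBC5", rna = "#DECBE4",
  microrna = "#FED9A6", complex = "#FBB4AE", phenotype = "#FFFFCC",
  metabolite = "#E5D8BD", drug = "#FDDAEC"
)

draw_entity <- function(img, e, f, background_mode) {
  x0 <- (e$x - e$w / 2) * f; x1 <- (e$x + e$w / 2) * f
  y0 <- (e$y - e$h / 2) * f; y1 <- (e$y + e$h / 2) * f
  if (background_mode == "bw") {
    fillc <- c(1, 1, 1); bord <- c(0.35, 0.35, 0.35)
  } else {
    fillc <- col_rgba01(.class_colors[[e$class]])[1:3]
    bord <- c(0.2, 0.2, 0.2)
  }
  img <- fill_rect(img, x0, y0, x1, y1, fillc, alpha = 0.9)
  outline_rect(img, x0, y0, x1, y1, bord, lw = max(1, f))
}

draw_overlay <- function(ov, img, f) {
  UseMethod("draw_overlay")
}

#' @export
draw_overlay.marker <- function(ov, img, f) {
  col <- col_rgba01(ov$color)[1:3]
  r <- max(3, 6 * f)
  verts <- shape_vertices("circle", ov$x * f, ov$y * f, 2 * r)
  img <- fill_convex(img, verts, col)
  tip <- cbind(c(ov$x * f, ov$x * f - r / 2, ov$x * f + r / 2),
               c(ov$y * f + 1.8 * r, ov$y * f + 0.5 * r, ov$y * f + 0.5 * r))
  fill_convex(img, tip, col)
}

#' @export
draw_overlay.heatmap_overlay <- function(ov, img, f) {
  cp <- ov$cell_px * f
  x0 <- (ov$x + ov$w / 2) * f
  y0 <- (ov$y - ov$h / 2) * f
  for (ri in seq_len(nrow(ov$colors))) {
    for (ci in seq_len(ncol(ov$colors))) {
      colhex <- ov$colors[ri, ci]
      col <- if (is.na(colhex)) c(0.8, 0.8, 0.8) else col_rgba01(colhex)[1:3]
      img <- fill_rect(img,
                       x0 + (ci - 1L) * cp, y0 + (ri - 1L) * cp,
                       x0 + ci * cp, y0 + ri * cp, col)
    }
  }
  outline_rect(img, x0, y0, x0 + ncol(ov$colors) * cp,
               y0 + nrow(ov$colors) * cp, c(0.3, 0.3, 0.3), lw = max(1, f / 2))
}

#' @export
draw_overlay.barplot_overlay <- function(ov, img, f) {
  bw <- 5 * f
  base <- (ov$y - ov$h / 2) * f
  x0 <- (ov$x - ov$w / 2) * f
  for (bi in seq_len(nrow(ov$bars))) {
    hpx <- ov$bars$height_px[bi] * f
    if (is.na(hpx)) next
    col <- col_rgba01(ov$bars$color[bi])[1:3]
    bx0 <- x0 + (bi - 1L) * (bw + f)
    if (hpx >= 0) {
      img <- fill_rect(img, bx0, base - hpx, bx0 + bw, base, col)
    } else {
      img <- fill_rect(img, bx0, base, bx0 + bw, base - hpx, col)
    }
  }
  img
}

#' @export
draw_overlay.glyph_overlay <- function(ov, img, f) {
  for (g in ov$glyphs) {
    off <- glyph_slot_offset(g$slot, ov$w, ov$h)
    rgba <- col_rgba01(g$color)
    verts <- shape_vertices(g$shape, (ov$x + off[1L]) * f,
                            (ov$y + off[2L]) * f, g$size_px * f)
    img <- fill_convex(img, verts, rgba[1:3], alpha = rgba[4L])
  }
  img
}

#' @export
draw_overlay.default <- function(ov, img, f) {
  stopf("cannot draw overlay of class '%s'", class(ov)[1L])
}

#' Write a raster image as PNG
#'
#' @param img array `[h, w, 3]` in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(img, path) {
  png::writePNG(img, target = path)
  invisible(path)
}

#' Render the full tile pyramid to disk
#'
#' One 256-px PNG tile per `(z, x, y)` address under
#' `out_dir/z/x/y.png`, `4^z` tiles at level `z`, for
#' `z = 0 .. max_zoom`.
#'
#' @param map a `network_map`.
#' @param out_dir output directory (created if needed).
#' @param staining,overlays,background_mode as in [render_level()].
#' @return a `tile_pyramid` description: `out_dir`, `levels`,
#'   `tile_counts`.
#' @export
build_tile_pyramid <- function(map, out_dir, staining = NULL,
                               overlays = list(), background_mode = NULL) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stopf("cannot create tile directory '%s'", out_dir)
  }
  counts <- integer(map$max_zoom + 1L)
  for (z in 0:map$max_zoom) {
    img <- render_level(map, z, staining = staining, overlays = overlays,
                        background_mode = background_mode)
    ntile <- 2L^z
    for (tx in 0:(ntile - 1L)) {
      dir.create(file.path(out_dir, z, tx), recursive = TRUE,
                 showWarnings = FALSE)
      for (ty in 0:(ntile - 1L)) {
        tile <- img[(ty * TILE_SIZE + 1L):((ty + 1L) * TILE_SIZE),
                    (tx * TILE_SIZE + 1L):((tx + 1L) * TILE_SIZE), ,
                    drop = FALSE]
        png::writePNG(tile, target = file.path(out_dir, z, tx,
                                               paste0(ty, ".png")))
        counts[z + 1L] <- counts[z + 1L] + 1L
      }
    }
  }
  structure(list(out_dir = out_dir, levels = 0:map$max_zoom,
                 tile_size = TILE_SIZE, tile_counts = counts),
            class = "tile_pyramid")
}

#' Stitch one pyramid level back into a single image
#'
#' @param pyramid a `tile_pyramid` (or the tile directory).
#' @param zoom level to stitch.
#' @return array `[256*2^z, 256*2^z, 3]`.
#' @export
stitch_level <- function(pyramid, zoom) {
  dirp <- if (inherits(pyramid, "tile_pyramid")) pyramid$out_dir else pyramid
  ntile <- 2L^as.integer(zoom)
  side <- ntile * TILE_SIZE
  out <- array(0, c(side, side, 3L))
  for (tx in 0:(ntile - 1L)) {
    for (ty in 0:(ntile - 1L)) {
      tile <- png::readPNG(file.path(dirp, zoom, tx, paste0(ty, ".png")))
      out[(ty * TILE_SIZE + 1L):((ty + 1L) * TILE_SIZE),
          (tx * TILE_SIZE + 1L):((tx + 1L) * TILE_SIZE), ] <- tile[, , 1:3]
    }
  }
  out
}
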