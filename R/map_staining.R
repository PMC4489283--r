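#' @title Map staining: Voronoi territories colored by data
#' @description
#' Map staining colors the background territory around each molecular
#' entity by a data value, so that large-scale trends (e.g. a whole
#' transcriptome) are visible at a glance on top of a large pathway map.
#' The territory of an entity is its Voronoi cell: the convex polygon of
#' all canvas points closer to that entity than to any other entity on the
#' map. Cells are built by clipping the canvas rectangle with the
#' perpendicular-bisector half-plane against every other site, and are
#' post-processed to avoid arbitrarily large territories in sparse regions
#' (see [limit_cell_extent()]).
#' @name map_staining
NULL

# --- convex polygon primitives -------------------------------------------

# Sutherland-Hodgman clip of polygon `poly` (n x 2 matrix) against the
# half-plane a*x + b*y <= c. Returns a (possibly empty) n x 2 matrix.
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1L] + b * poly[, 2L] - c
  eps <- 1e-9 * (abs(c) + 1)
  inside <- d <= eps
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[integer(0), , drop = FALSE])
  out <- matrix(0, nrow = 0L, ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Shoelace area of a simple polygon.
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Vectorized membership test for a convex polygon (vertices in consistent
# winding order): a point is inside iff it lies on one side of every edge.
points_in_convex <- function(poly, px, py, tol = 1e-7) {
  n <- nrow(poly)
  if (n < 3L) return(rep(FALSE, length(px)))
  # establish winding sign from the polygon itself
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(2:n, 1L)
  sgn <- sign(sum(x * y[j] - x[j] * y))
  if (sgn == 0) return(rep(FALSE, length(px)))
  ok <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    k <- j[i]
    cross <- (x[k] - x[i]) * (py - y[i]) - (y[k] - y[i]) * (px - x[i])
    ok <- ok & (sgn * cross >= -tol)
  }
  ok
}

# --- Voronoi construction -------------------------------------------------

#' Compute canvas-clipped Voronoi cells for map entities
#'
#' Each site owns the convex polygon of canvas points nearer to it
#' (Euclidean) than to any other site. Sites at exactly coincident
#' coordinates are merged into one cell owning all their entity ids.
#' Before extent limiting the cells tile the canvas exactly.
#'
#' @param sites data.frame with columns `entity_id`, `x`, `y` (map pixels).
#' @param canvas numeric `c(width, height)`.
#' @return a `voronoi_cells` list; each cell has `entity_ids`, `site`
#'   (x, y), `polygon` (vertex matrix, counter-clockwise in y-down pixel
#'   coordinates), `area` and a `clipped` flag (FALSE here, set by
#'   [limit_cell_extent()]).
#' @export
compute_voronoi <- function(sites, canvas) {
  w <- canvas[[1L]]; h <- canvas[[2L]]
  if (nrow(sites) == 0L) stopf("compute_voronoi: no sites")
  if (any(sites$x < 0 | sites$x >= w | sites$y < 0 | sites$y >= h)) {
    bad <- which(sites$x < 0 | sites$x >= w | sites$y < 0 | sites$y >= h)[1L]
    stopf("site '%s' at (%g, %g) lies outside the %g x %g canvas",
          sites$entity_id[bad], sites$x[bad], sites$y[bad], w, h)
  }
  key <- paste(sites$x, sites$y)
  uniq <- !duplicated(key)
  ux <- sites$x[uniq]; uy <- sites$y[uniq]; ukey <- key[uniq]
  ids_of <- split(as.character(sites$entity_id), factor(key, levels = ukey))
  m <- length(ux)
  rect <- matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2L, byrow = TRUE)
  cells <- vector("list", m)
  for (i in seq_len(m)) {
    poly <- rect
    for (k in seq_len(m)) {
      if (k == i) next
      # closer to site i than to site k:
      # 2(xk-xi) x + 2(yk-yi) y <= xk^2 - xi^2 + yk^2 - yi^2
      a <- 2 * (ux[k] - ux[i]); b <- 2 * (uy[k] - uy[i])
      cc <- ux[k]^2 - ux[i]^2 + uy[k]^2 - uy[i]^2
      poly <- clip_halfplane(poly, a, b, cc)
      if (nrow(poly) == 0L) break
    }
    cells[[i]] <- structure(list(
      entity_ids = ids_of[[i]], site = c(x = ux[i], y = uy[i]),
      polygon = poly, area = polygon_area(poly), clipped = FALSE
    ), class = "voronoi_cell")
  }
  structure(cells, class = "voronoi_cells",
            canvas = c(width = w, height = h))
}

#' Limit Voronoi cell extent around each site
#'
#' Unbounded border territories dominate sparse regions of a map; each
#' cell is therefore intersected with the axis-aligned square of
#' half-width `R` centered on its site, where `R = radius_factor` times
#' the median nearest-neighbor distance among sites (scale-free per map),
#' or an absolute `radius` when given. Cells whose polygon changed get
#' their `clipped` flag set. The operation is contractive and idempotent.
#'
#' @param cells a `voronoi_cells` object from [compute_voronoi()].
#' @param radius_factor multiple of the median nearest-neighbor site
#'   distance (default 3; must be > 0). Use `Inf` to disable limiting.
#' @param radius absolute half-width in pixels, overriding `radius_factor`.
#' @return the clipped `voronoi_cells`, with attribute `radius`.
#' @export
limit_cell_extent <- function(cells, radius_factor = 3, radius = NULL) {
  if (is.null(radius)) {
    if (radius_factor <= 0) stopf("radius_factor must be > 0")
    R <- radius_factor * median_nn_distance(cells)
  } else {
    if (radius <= 0) stopf("radius must be > 0")
    R <- radius
  }
  if (!is.finite(R)) return(cells)
  out <- lapply(cells, function(cell) {
    sx <- cell$site[["x"]]; sy <- cell$site[["y"]]
    poly <- cell$polygon
    poly <- clip_halfplane(poly,  1,  0, sx + R)
    poly <- clip_halfplane(poly, -1,  0, -(sx - R))
    poly <- clip_halfplane(poly,  0,  1, sy + R)
    poly <- clip_halfplane(poly,  0, -1, -(sy - R))
    area <- polygon_area(poly)
    changed <- abs(area - cell$area) > 1e-9 * (cell$area + 1)
    cell$polygon <- poly
    cell$area <- area
    cell$clipped <- cell$clipped || changed
    cell
  })
  structure(out, class = "voronoi_cells", canvas = attr(cells, "canvas"),
            radius = R)
}

# Median over sites of the distance to the nearest other site; Inf for a
# single site (nothing to compare against, so no limiting applies).
median_nn_distance <- function(cells) {
  xs <- vapply(cells, function(c) c$site[["x"]], 0)
  ys <- vapply(cells, function(c) c$site[["y"]], 0)
  n <- length(xs)
  if (n < 2L) return(Inf)
  d <- as.matrix(stats::dist(cbind(xs, ys)))
  diag(d) <- Inf
  stats::median(apply(d, 1L, min))
}

#' Build a map-staining layer from per-gene values
#'
#' Every entity on the map is a Voronoi site (each alias occurrence has
#' its own territory). An entity whose symbols carry at least one value
#' gets its cell filled with `value_to_color(scale, v)`, where `v` is the
#' mean over its valued symbols (relevant for complexes); entities with no
#' value stay unstained. When staining is active the map itself is drawn
#' in black and white so the territory colors are not mixed with the map's
#' own decoration.
#'
#' @param map a `network_map`.
#' @param gene_values named numeric vector, canonical symbol -> value
#'   (e.g. a [summarize_group()] result).
#' @param scale a `color_scale`; default: green-white-red gradient
#'   anchored at the min / median / max of the mapped entity values.
#' @param opacity global stain opacity in `[0, 1]`.
#' @param background_mode `"bw"` (default) or `"color"`.
#' @param radius_factor,radius extent limiting, see [limit_cell_extent()].
#' @return a `staining_layer`: `cells`, `values` (per cell, NA =
#'   unstained), `fill` (per-cell `#RRGGBBAA` or NA), `opacity`,
#'   `background_mode`, `scale`.
#' @export
build_staining_layer <- function(map, gene_values, scale = NULL,
                                 opacity = 0.7, background_mode = c("bw", "color"),
                                 radius_factor = 3, radius = NULL) {
  background_mode <- match.arg(background_mode)
  if (opacity < 0 || opacity > 1) stopf("opacity must be in [0, 1]")
  names(gene_values) <- canon_symbol(names(gene_values))
  sites <- data.frame(
    entity_id = vapply(map$entities, `[[`, "", "id"),
    x = vapply(map$entities, `[[`, 0, "x"),
    y = vapply(map$entities, `[[`, 0, "y"),
    stringsAsFactors = FALSE
  )
  cells <- compute_voronoi(sites, c(map$canvas_width, map$canvas_height))
  cells <- limit_cell_extent(cells, radius_factor = radius_factor,
                             radius = radius)
  ent_value <- entity_values(map, gene_values)
  cell_vals <- vapply(cells, function(cell) {
    v <- ent_value[cell$entity_ids]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  if (is.null(scale)) scale <- default_expression_scale(cell_vals)
  fill <- rep(NA_character_, length(cells))
  has <- !is.na(cell_vals)
  if (any(has)) fill[has] <- value_to_color(scale, cell_vals[has])
  structure(list(
    cells = cells, values = cell_vals, fill = fill, opacity = opacity,
    background_mode = background_mode, scale = scale
  ), class = "staining_layer")
}

# Per-entity value: mean over the entity's symbols that carry a value.
entity_values <- function(map, gene_values) {
  out <- vapply(map$entities, function(e) {
    v <- gene_values[names(gene_values) %in% e$hugo]
    if (length(v) == 0L || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  names(out) <- vapply(map$entities, `[[`, "", "id")
  out
}

#' Export a staining layer as SVG polygons
#'
#' @param layer a `staining_layer`.
#' @param path optional output file.
#' @return the SVG text (invisibly when written).
#' @export
staining_to_svg <- function(layer, path = NULL) {
  canvas <- attr(layer$cells, "canvas")
  poly_tags <- mapply(function(cell, fill) {
    pts <- paste(apply(cell$polygon, 1L, function(p)
      sprintf("%.3f,%.3f", p[1L], p[2L])), collapse = " ")
    col <- if (is.na(fill)) "#DDDDDD" else substr(fill, 1L, 7L)
    op <- if (is.na(fill)) 0.15 else layer$opacity
    sprintf('  <polygon points="%s" fill="%s" fill-opacity="%.3f" stroke="#888888" stroke-width="0.5"/>',
            pts, col, op)
  }, layer$cells, layer$fill)
  txt <- paste(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g">',
            canvas[["width"]], canvas[["height"]]),
    poly_tags, "</svg>", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
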