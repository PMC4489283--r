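#' @title Entity-anchored overlays
#' @description
#' Four overlay kinds attach to entity positions: simple markers
#' (search-result pictograms), heatmap grids (data tables x samples or
#' groups), barplots (bar height proportional to value) and glyphs (up to
#' five small geometric shapes per entity whose shape / color / size
#' channels can each be driven by a different data table).
#' @name overlays
NULL

#' Place markers for a list of gene symbols
#'
#' One marker per matched entity occurrence: a symbol present as a free
#' protein and inside a complex yields two markers. Unmatched symbols are
#' reported, not dropped silently.
#'
#' @param map a `network_map`.
#' @param symbols character vector of gene symbols.
#' @param color marker color.
#' @return `list(markers, unmatched)`; each marker is
#'   `list(entity_id, x, y, label, color)` anchored at the entity position.
#' @export
build_markers <- function(map, symbols, color = "#D62728") {
  res <- resolve_symbols(map, symbols)
  ents <- stats::setNames(map$entities, vapply(map$entities, `[[`, "", "id"))
  markers <- list()
  for (s in names(res$matched)) {
    for (id in res$matched[[s]]) {
      e <- ents[[id]]
      markers[[length(markers) + 1L]] <- structure(
        list(entity_id = id, x = e$x, y = e$y, label = s, color = color),
        class = "marker")
    }
  }
  list(markers = markers, unmatched = res$unmatched)
}

# Value of one entity in one table for one column spec (a sample id or a
# sample_group). Continuous channels average over the entity's symbols;
# mutation channels flag "any symbol mutated".
entity_cell_value <- function(map, entity, table, column) {
  syms <- intersect(entity$hugo, table$genes)
  if (length(syms) == 0L) return(NA)
  vals <- if (inherits(column, "sample_group")) {
    summarize_group(table, column)[syms]
  } else {
    if (!column %in% table$samples) return(NA)
    v <- table$values[syms, column]
    if (table$internal_repr == "discrete_unordered") is_mutated(v)
    else if (table$internal_repr == "set") as.logical(v)
    else as.numeric(v)
  }
  if (all(is.na(vals))) return(NA)
  if (table$internal_repr %in% c("continuous", "discrete_ordered")) {
    mean(vals, na.rm = TRUE)
  } else {
    any(vals, na.rm = TRUE)
  }
}

column_label <- function(column) {
  if (inherits(column, "sample_group")) column$group_id else as.character(column)
}

#' Build a heatmap overlay for one entity
#'
#' Grid with one row per data table and one column per selected sample or
#' group; each cell is colored through that table's scale. Missing cells
#' stay marked missing.
#'
#' @param map a `network_map`.
#' @param entity_id the anchor entity.
#' @param tables named list of `omics_table`s (the rows).
#' @param columns list of sample ids and/or `sample_group`s (the columns).
#' @param scales named list of `color_scale`s, one per table; defaults per
#'   internal representation (expression gradient / copy-number palette).
#' @param cell_px cell edge length in pixels.
#' @return a `heatmap_overlay` (`values`, `colors`, rectangular grids), or
#'   `NULL` when the entity has no data in any table (caller skips it).
#' @export
build_heatmap <- function(map, entity_id, tables, columns, scales = NULL,
                          cell_px = 10) {
  entity <- find_entity(map, entity_id)
  if (is.null(names(tables))) names(tables) <- vapply(tables, `[[`, "", "name")
  vals <- matrix(NA_real_, nrow = length(tables), ncol = length(columns),
                 dimnames = list(names(tables),
                                 vapply(columns, column_label, "")))
  cols <- matrix(NA_character_, nrow = nrow(vals), ncol = ncol(vals),
                 dimnames = dimnames(vals))
  for (ti in seq_along(tables)) {
    tab <- tables[[ti]]
    scale <- scales[[names(tables)[ti]]] %||% default_table_scale(tab)
    for (ci in seq_along(columns)) {
      v <- entity_cell_value(map, entity, tab, columns[[ci]])
      if (is.na(v)) next
      vals[ti, ci] <- as.numeric(v)
      cols[ti, ci] <- value_to_color(scale, as.numeric(v))
    }
  }
  if (all(is.na(vals))) return(NULL)
  structure(list(entity_id = entity$id, x = entity$x, y = entity$y,
                 w = entity$w, h = entity$h,
                 values = vals, colors = cols, cell_px = cell_px),
            class = "heatmap_overlay")
}

default_table_scale <- function(table) {
  switch(table$internal_repr,
    continuous = default_expression_scale(table$values),
    discrete_ordered = default_copynumber_palette(),
    # logical channels (mutation / set flags, coerced to 0/1)
    ordered_palette(lower = c(0, 1), upper = c(0, 1),
                    colors = c("#FFFFFF", "#00FFFF"))
  )
}

#' Build a barplot overlay for one entity
#'
#' Bars are drawn above the entity, heights proportional to
#' `value / global_max * max_height_px`. The normalizing maximum is the
#' per-data-table global maximum absolute value, so bar heights are
#' comparable across the whole map; negative values draw downward from
#' the baseline.
#'
#' @param map,entity_id anchor entity.
#' @param table a continuous or discrete-ordered `omics_table`.
#' @param columns list of sample ids and/or `sample_group`s.
#' @param colors bar colors, recycled over columns.
#' @param max_height_px height of a bar at the global maximum.
#' @param global_max normalizing value; default `max(abs(table$values))`.
#' @return a `barplot_overlay` with a `bars` data.frame
#'   (`label, value, height_px, color`), or `NULL` when no data.
#' @export
build_barplot <- function(map, entity_id, table, columns,
                          colors = c("#4477AA", "#EE6677", "#228833",
                                     "#CCBB44", "#66CCEE"),
                          max_height_px = 40, global_max = NULL) {
  entity <- find_entity(map, entity_id)
  if (!table$internal_repr %in% c("continuous", "discrete_ordered")) {
    stopf("barplots need a numeric table, not '%s'", table$internal_repr)
  }
  if (is.null(global_max)) {
    global_max <- max(abs(table$values), na.rm = TRUE)
  }
  if (!is.finite(global_max) || global_max <= 0) {
    stopf("barplot normalization needs a positive global maximum")
  }
  vals <- vapply(columns, function(cl)
    as.numeric(entity_cell_value(map, entity, table, cl)), 0)
  if (all(is.na(vals))) return(NULL)
  bars <- data.frame(
    label = vapply(columns, column_label, ""),
    value = vals,
    height_px = vals / global_max * max_height_px,
    color = rep_len(colors, length(columns)),
    stringsAsFactors = FALSE
  )
  structure(list(entity_id = entity$id, x = entity$x, y = entity$y,
                 w = entity$w, h = entity$h, bars = bars,
                 max_height_px = max_height_px, global_max = global_max),
            class = "barplot_overlay")
}

.glyph_shapes <- c("triangle", "square", "circle", "diamond", "hexagon")
.glyph_capacity <- 5L

#' Create an empty glyph overlay for an entity
#'
#' @param map,entity_id anchor entity.
#' @return a `glyph_overlay` with no glyphs.
#' @export
glyph_overlay <- function(map, entity_id) {
  entity <- find_entity(map, entity_id)
  structure(list(entity_id = entity$id, x = entity$x, y = entity$y,
                 w = entity$w, h = entity$h, glyphs = list()),
            class = "glyph_overlay")
}

#' Attach a glyph to an entity
#'
#' At most five glyphs fit on one entity, in five fixed slots around its
#' bounding box (four corners plus top-center). Each channel (shape,
#' color, size) may come from a different data table — e.g. shape from
#' copy-number state, color from expression, size from mutation
#' frequency — resolved by the caller into concrete values.
#'
#' @param overlay a `glyph_overlay`.
#' @param shape one of triangle, square, circle, diamond, hexagon.
#' @param color glyph color (default cyan, the mutation convention).
#' @param size_px glyph edge/diameter in pixels; see
#'   [glyph_size_from_value()] to derive it from a value such as a
#'   mutation frequency.
#' @return the overlay with the glyph appended in the next free slot.
#' @export
attach_glyph <- function(overlay, shape = "triangle", color = "#00FFFF",
                         size_px = 12) {
  shape <- match.arg(shape, .glyph_shapes)
  if (length(overlay$glyphs) >= .glyph_capacity) {
    stopf("entity '%s' already carries %d glyphs (the maximum)",
          overlay$entity_id, .glyph_capacity)
  }
  if (size_px <= 0) stopf("glyph size must be positive")
  slot <- length(overlay$glyphs) + 1L
  overlay$glyphs[[slot]] <- list(shape = shape, color = hex_rgba(color),
                                 size_px = size_px, slot = slot)
  overlay
}

#' Affine value-to-size mapping for glyphs
#'
#' Maps `value` linearly from `[vmin, vmax]` onto `[smin_px, smax_px]`,
#' clamping outside the value range — e.g. glyph size proportional to a
#' gene's mutation frequency.
#'
#' @param value numeric value(s).
#' @param vmin,vmax value range (`vmin < vmax`).
#' @param smin_px,smax_px pixel size range (`smin_px <= smax_px`).
#' @return size(s) in pixels.
#' @export
glyph_size_from_value <- function(value, vmin, vmax, smin_px, smax_px) {
  if (vmin >= vmax) stopf("glyph size mapping needs vmin < vmax")
  if (smin_px > smax_px) stopf("glyph size mapping needs smin_px <= smax_px")
  t <- pmin(1, pmax(0, (value - vmin) / (vmax - vmin)))
  smin_px + t * (smax_px - smin_px)
}

find_entity <- function(map, entity_id) {
  for (e in map$entities) if (e$id == entity_id) return(e)
  stopf("no entity '%s' on map '%s'", entity_id, map$name)
}

# Fixed glyph slot anchors around the entity bounding box:
# 1 top-left, 2 top-right, 3 bottom-right, 4 bottom-left, 5 top-center.
glyph_slot_offset <- function(slot, w, h) {
  switch(slot,
    c(-w / 2, -h / 2), c(w / 2, -h / 2), c(w / 2, h / 2),
    c(-w / 2, h / 2), c(0, -h / 2))
}

#' Serialize a set of overlays to a JSON layer file
#'
#' @param overlays list of overlay objects (markers, heatmaps, barplots,
#'   glyph overlays).
#' @param path optional output file.
#' @return JSON text (invisibly when written).
#' @export
overlays_to_json <- function(overlays, path = NULL) {
  enc <- lapply(overlays, function(ov) {
    kind <- class(ov)[1L]
    body <- unclass(ov)
    body$kind <- kind
    body
  })
  txt <- as.character(jsonlite::toJSON(enc, auto_unbox = TRUE, digits = NA,
                                       pretty = 2L, na = "null"))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
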