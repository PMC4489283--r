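#' @title Positioned network maps
#' @description
#' A network map is a fixed-layout picture of a molecular network: every
#' molecular species (protein, gene, RNA, complex, phenotype, ...) has a
#' position on a pixel canvas, a set of HUGO gene-symbol aliases used to
#' join omics data rows to it, a set of module memberships, and the zoom
#' level at which it first becomes visible (semantic zoom). Maps are
#' exchanged as a self-contained JSON descriptor; see [load_map()].
#' @name map_model
NULL

.entity_classes <- c("protein", "gene", "rna", "microrna", "complex",
                     "phenotype", "metabolite", "drug")

#' Construct a map entity
#'
#' @param id unique entity identifier (opaque string).
#' @param label display label; defaults to `id`.
#' @param class entity class, one of protein, gene, rna, microrna, complex,
#'   phenotype, metabolite, drug.
#' @param hugo character vector of HUGO symbol aliases (canonicalized to
#'   uppercase; may be empty, e.g. for phenotypes; a complex lists the
#'   symbols of its components). Duplicates are dropped silently.
#' @param x,y entity anchor position in map pixels, origin top-left,
#'   y increasing downward.
#' @param w,h bounding-box width and height in pixels.
#' @param modules character vector of module ids this entity belongs to.
#' @param min_zoom smallest integer zoom level at which the entity is drawn.
#' @return a `map_entity` object.
#' @export
map_entity <- function(id, label = id, class = "protein", hugo = character(),
                       x, y, w = 40, h = 20, modules = character(),
                       min_zoom = 0L) {
  class <- match.arg(class, .entity_classes)
  if (min_zoom < 0) stopf("entity '%s': min_zoom must be >= 0", id)
  e <- list(
    id = as.character(id), label = as.character(label), class = class,
    hugo = unique(canon_symbol(hugo)),
    x = as.numeric(x), y = as.numeric(y),
    w = as.numeric(w), h = as.numeric(h),
    modules = as.character(modules), min_zoom = as.integer(min_zoom)
  )
  structure(e, class = "map_entity")
}

#' Construct a network map
#'
#' @param name map name.
#' @param canvas_width,canvas_height canvas dimensions in pixels (> 0).
#' @param max_zoom deepest zoom level (>= 0).
#' @param entities list of [map_entity()] objects.
#' @param modules list of modules, each `list(id =, name =, members =)`
#'   where `members` are entity ids.
#' @return a validated `network_map` object.
#' @export
network_map <- function(name, canvas_width, canvas_height, max_zoom = 0L,
                        entities = list(), modules = list()) {
  m <- structure(list(
    name = as.character(name),
    canvas_width = as.numeric(canvas_width),
    canvas_height = as.numeric(canvas_height),
    max_zoom = as.integer(max_zoom),
    entities = entities,
    modules = modules
  ), class = "network_map")
  validate_map(m)
  m
}

#' Validate a network map's structural invariants
#'
#' Checks canvas dimensions, entity id uniqueness, on-canvas positions,
#' zoom-level consistency and module referential integrity. Errors name
#' the offending entity or module id.
#'
#' @param map a `network_map`.
#' @return the map, invisibly, if valid.
#' @export
validate_map <- function(map) {
  if (!inherits(map, "network_map")) stopf("not a network_map")
  if (map$canvas_width <= 0 || map$canvas_height <= 0) {
    stopf("map '%s': canvas dimensions must be positive", map$name)
  }
  if (map$max_zoom < 0) stopf("map '%s': max_zoom must be >= 0", map$name)
  ids <- vapply(map$entities, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stopf("duplicate entity id '%s'", ids[duplicated(ids)][1L])
  }
  for (e in map$entities) {
    if (e$x < 0 || e$x >= map$canvas_width ||
        e$y < 0 || e$y >= map$canvas_height) {
      stopf("entity '%s': position (%g, %g) outside canvas", e$id, e$x, e$y)
    }
    if (e$min_zoom > map$max_zoom) {
      stopf("entity '%s': min_zoom %d exceeds map max_zoom %d",
            e$id, e$min_zoom, map$max_zoom)
    }
  }
  for (mod in map$modules) {
    if (length(mod$members) == 0L) {
      stopf("module '%s': empty member list", mod$id)
    }
    missing <- setdiff(mod$members, ids)
    if (length(missing)) {
      stopf("module '%s' references missing entity '%s'", mod$id, missing[1L])
    }
  }
  invisible(map)
}

# Byte offset of a JSON syntax error, from the validator's diagnostics.
json_error_offset <- function(txt) {
  v <- jsonlite::validate(txt)
  off <- attr(v, "offset")
  if (is.null(off)) off <- nchar(txt, type = "bytes")
  as.integer(off)
}

#' Load a network map from a JSON descriptor
#'
#' The descriptor dialect has top-level keys `name`,
#' `canvas: {width, height, max_zoom}`,
#' `entities: [{id, label, class, hugo, x, y, w, h, modules, min_zoom}]`
#' and `modules: [{id, name, members}]`. `hugo` and `modules` default to
#' empty lists and `min_zoom` to 0. Coordinates are map pixels with origin
#' top-left and y increasing downward.
#'
#' @param x path to a JSON file, or the JSON text itself.
#' @return a validated `network_map`.
#' @seealso [save_map()] for the inverse; `save_map(load_map(d))` is
#'   byte-identical to `d` for canonical descriptors.
#' @export
load_map <- function(x) {
  txt <- read_text_arg(x, "map descriptor")
  d <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stopf("malformed JSON in map descriptor (parse error near byte offset %d)",
            json_error_offset(txt))
    }
  )
  canvas <- d$canvas %||% stopf("map descriptor missing 'canvas'")
  entities <- lapply(d$entities %||% list(), function(e) {
    map_entity(
      id = e$id, label = e$label %||% e$id,
      class = e$class %||% "protein",
      hugo = unlist(e$hugo) %||% character(),
      x = e$x, y = e$y, w = e$w %||% 40, h = e$h %||% 20,
      modules = unlist(e$modules) %||% character(),
      min_zoom = e$min_zoom %||% 0L
    )
  })
  modules <- lapply(d$modules %||% list(), function(m) {
    list(id = as.character(m$id), name = as.character(m$name %||% m$id),
         members = as.character(unlist(m$members)))
  })
  network_map(
    name = d$name %||% "map",
    canvas_width = canvas$width, canvas_height = canvas$height,
    max_zoom = canvas$max_zoom %||% 0L,
    entities = entities, modules = modules
  )
}

#' Serialize a network map to its canonical JSON descriptor
#'
#' The writer is deterministic: fixed key order, two-space indentation,
#' full numeric precision. Loading and re-saving a canonical descriptor
#' reproduces it byte for byte.
#'
#' @param map a `network_map`.
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return the JSON text (invisibly when written to `path`).
#' @export
save_map <- function(map, path = NULL) {
  validate_map(map)
  ub <- jsonlite::unbox
  num <- function(v) ub(if (v == as.integer(v)) as.integer(v) else v)
  d <- list(
    name = ub(map$name),
    canvas = list(width = num(map$canvas_width),
                  height = num(map$canvas_height),
                  max_zoom = ub(map$max_zoom)),
    entities = lapply(map$entities, function(e) list(
      id = ub(e$id), label = ub(e$label), class = ub(e$class),
      hugo = as.list(e$hugo),
      x = num(e$x), y = num(e$y), w = num(e$w), h = num(e$h),
      modules = as.list(e$modules), min_zoom = ub(e$min_zoom)
    )),
    modules = lapply(map$modules, function(m) list(
      id = ub(m$id), name = ub(m$name), members = as.list(m$members)
    ))
  )
  txt <- as.character(jsonlite::toJSON(d, digits = NA, pretty = 2L))
  txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Index map entities by canonical HUGO symbol
#'
#' Every entity listing a symbol appears under that symbol, so a symbol
#' carried by a free protein and by a complex containing it maps to both
#' entity ids.
#'
#' @param map a `network_map`.
#' @return named list, canonical symbol -> character vector of entity ids,
#'   sorted by symbol.
#' @export
symbol_index <- function(map) {
  idx <- list()
  for (e in map$entities) {
    for (s in e$hugo) idx[[s]] <- c(idx[[s]], e$id)
  }
  idx[order(names(idx))]
}

#' Distinct symbols present on a map
#'
#' @param map a `network_map`.
#' @return sorted character vector of distinct canonical symbols.
#' @export
map_symbols <- function(map) {
  sort(unique(unlist(lapply(map$entities, `[[`, "hugo"))))
}

#' Resolve user symbols against a map
#'
#' Input symbols are canonicalized and deduplicated, then partitioned into
#' those present on the map (with their entity ids) and those absent.
#'
#' @param map a `network_map`.
#' @param symbols character vector of gene symbols.
#' @return `list(matched = <symbol -> entity ids>, unmatched = <character>)`.
#' @export
resolve_symbols <- function(map, symbols) {
  symbols <- unique(canon_symbol(symbols))
  symbols <- symbols[nzchar(symbols)]
  idx <- symbol_index(map)
  hit <- symbols %in% names(idx)
  list(matched = idx[symbols[hit]], unmatched = symbols[!hit])
}

#' Entities visible at a zoom level
#'
#' Semantic zoom: an entity is drawn at zoom `z` iff its `min_zoom <= z`,
#' so the visible set grows monotonically with zoom.
#'
#' @param map a `network_map`.
#' @param zoom integer zoom level in `[0, max_zoom]`.
#' @return list of `map_entity` objects.
#' @export
visible_entities <- function(map, zoom) {
  if (zoom < 0 || zoom > map$max_zoom) {
    stopf("zoom %s out of range [0, %d]", format(zoom), map$max_zoom)
  }
  Filter(function(e) e$min_zoom <= zoom, map$entities)
}

#' @export
print.network_map <- function(x, ...) {
  cat(sprintf("network_map '%s': %dx%d px, max_zoom %d, %d entities, %d modules\n",
              x$name, x$canvas_width, x$canvas_height, x$max_zoom,
              length(x$entities), length(x$modules)))
  invisible(x)
}
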