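#' @title Session-based JSON command engine
#' @description
#' The automation surface mirrors a RESTful visualization service: a
#' session with a unique id holds a loaded map, imported data tables,
#' sample groups and active layers, and is driven by JSON-encoded
#' commands (`action` + `params`). The engine is in-process; the JSON
#' command vocabulary is the binding surface for scripts and for the
#' batch CLI, which records commands to a log and replays them here.
#' @name service_cli
NULL

.sessions <- new.env(parent = emptyenv())
.session_counter <- new.env(parent = emptyenv())

#' Create a fresh session
#'
#' @return the session id: a 128-bit random hex token, unique for the
#'   process lifetime.
#' @export
create_session <- function() {
  n <- (.session_counter$n %||% 0L) + 1L
  .session_counter$n <- n
  repeat {
    tok <- paste(c(
      format(as.hexmode(sample.int(65536L, 6L, replace = TRUE) - 1L),
             width = 4L),
      sprintf("%08x", n)), collapse = "")
    if (is.null(.sessions[[tok]])) break
  }
  st <- new.env(parent = emptyenv())
  st$map <- NULL
  st$tables <- list()
  st$groups <- list()
  st$staining <- NULL
  st$overlays <- list()
  .sessions[[tok]] <- st
  tok
}

#' Destroy a session
#' @param session_id the id to drop.
#' @return `TRUE` if the session existed.
#' @export
destroy_session <- function(session_id) {
  existed <- !is.null(.sessions[[session_id]])
  if (existed) rm(list = session_id, envir = .sessions)
  existed
}

#' Access a session's state
#'
#' Mainly for programmatic front ends (the batch CLI) that need the
#' loaded objects after replaying a command log.
#'
#' @param session_id a session id.
#' @return the session state environment (`map`, `tables`, `groups`,
#'   `staining`, `overlays`), or an error for unknown sessions.
#' @export
session_state <- function(session_id) {
  st <- .sessions[[session_id]]
  if (is.null(st)) stopf("unknown session '%s'", session_id)
  st
}

cmd_error <- function(code, message) {
  list(status = "error", code = code, error = message)
}

cmd_ok <- function(payload = NULL) {
  list(status = "ok", payload = payload)
}

#' Execute a JSON command against a session
#'
#' Supported actions: `load_map`, `import_datatable`, `define_groups`,
#' `set_staining`, `add_overlay`, `render`, `enrich`, `list_hugo`.
#' Responses always carry a `status` plus a `payload` (ok) or `error`
#' with a numeric `code` (404 unknown session, 400 bad command).
#'
#' @param session_id a session id from [create_session()].
#' @param command a JSON string `{"action": ..., "params": {...}}` or the
#'   equivalent list.
#' @return the response list.
#' @export
execute_command <- function(session_id, command) {
  st <- .sessions[[session_id]]
  if (is.null(st)) return(cmd_error(404L, sprintf("unknown session '%s'",
                                                  session_id)))
  if (is.character(command)) {
    command <- tryCatch(jsonlite::fromJSON(command, simplifyVector = FALSE),
                        error = function(e) NULL)
    if (is.null(command)) return(cmd_error(400L, "command is not valid JSON"))
  }
  action <- command$action
  params <- command$params %||% list()
  known <- c("load_map", "import_datatable", "define_groups", "set_staining",
             "add_overlay", "render", "enrich", "list_hugo")
  if (is.null(action) || !action %in% known) {
    return(cmd_error(400L, sprintf(
      "unknown action '%s'; known actions: %s",
      action %||% "<missing>", paste(known, collapse = ", "))))
  }
  tryCatch(
    do.call(paste0("cmd_", action), list(st, params)),
    error = function(e) cmd_error(400L, conditionMessage(e))
  )
}

need_map <- function(st) {
  if (is.null(st$map)) stopf("no map loaded in this session")
  st$map
}

cmd_load_map <- function(st, params) {
  src <- params$descriptor %||% params$path %||%
    stopf("load_map needs 'descriptor' (JSON text) or 'path'")
  st$map <- load_map(src)
  cmd_ok(list(name = st$map$name,
              entities = length(st$map$entities),
              modules = length(st$map$modules)))
}

cmd_import_datatable <- function(st, params) {
  type <- params$type %||% stopf("import_datatable needs 'type'")
  src <- params$text %||% params$path %||%
    stopf("import_datatable needs 'text' or 'path'")
  name <- params$name %||% type
  st$tables[[name]] <- parse_data_table(src, data_type = type, name = name)
  tab <- st$tables[[name]]
  cmd_ok(list(name = name, internal_repr = tab$internal_repr,
              genes = length(tab$genes), samples = length(tab$samples)))
}

cmd_define_groups <- function(st, params) {
  src <- params$annotation %||% params$path %||%
    stopf("define_groups needs 'annotation' or 'path'")
  factor <- params$factor %||% stopf("define_groups needs 'factor'")
  ann <- parse_sample_annotation(src)
  gs <- build_groups(ann, factor)
  for (g in gs) st$groups[[g$group_id]] <- g
  cmd_ok(list(groups = vapply(gs, `[[`, "", "group_id")))
}

session_column <- function(st, params) {
  if (!is.null(params$group)) {
    st$groups[[params$group]] %||%
      stopf("unknown group '%s'", params$group)
  } else if (!is.null(params$sample)) {
    params$sample
  } else {
    stopf("need 'group' or 'sample'")
  }
}

session_gene_values <- function(st, params) {
  tab <- st$tables[[params$table %||% stopf("need 'table'")]] %||%
    stopf("unknown table '%s'", params$table)
  column <- session_column(st, params)
  if (inherits(column, "sample_group")) {
    summarize_group(tab, column)
  } else {
    if (!column %in% tab$samples) stopf("unknown sample '%s'", column)
    v <- tab$values[, column]
    if (tab$internal_repr == "discrete_unordered") {
      v <- as.numeric(is_mutated(v))
    }
    stats::setNames(as.numeric(v), tab$genes)
  }
}

cmd_set_staining <- function(st, params) {
  map <- need_map(st)
  vals <- session_gene_values(st, params)
  scale <- if (identical(params$scale %||% "default", "default")) NULL
           else stopf("only the default scale is addressable by name")
  st$staining <- build_staining_layer(
    map, vals, scale = scale,
    opacity = params$opacity %||% 0.7,
    background_mode = params$background %||% "bw",
    radius_factor = params$radius_factor %||% 3
  )
  cmd_ok(list(stained = sum(!is.na(st$staining$fill)),
              cells = length(st$staining$cells)))
}

cmd_add_overlay <- function(st, params) {
  map <- need_map(st)
  kind <- params$kind %||% stopf("add_overlay needs 'kind'")
  ov <- switch(kind,
    marker = {
      built <- build_markers(map, unlist(params$symbols))
      st$overlays <- c(st$overlays, built$markers)
      return(cmd_ok(list(markers = length(built$markers),
                         unmatched = built$unmatched)))
    },
    heatmap = {
      tabs <- st$tables[unlist(params$tables)]
      cols <- lapply(unlist(params$columns), function(cn)
        st$groups[[cn]] %||% cn)
      build_heatmap(map, params$entity, tabs, cols)
    },
    barplot = {
      tab <- st$tables[[params$table]] %||% stopf("unknown table '%s'",
                                                  params$table)
      cols <- lapply(unlist(params$columns), function(cn)
        st$groups[[cn]] %||% cn)
      build_barplot(map, params$entity, tab, cols)
    },
    glyph = {
      g <- glyph_overlay(map, params$entity)
      attach_glyph(g, shape = params$shape %||% "triangle",
                   color = params$color %||% "#00FFFF",
                   size_px = params$size_px %||% 12)
    },
    stopf("unknown overlay kind '%s'", kind)
  )
  if (is.null(ov)) return(cmd_ok(list(skipped = TRUE)))
  st$overlays <- c(st$overlays, list(ov))
  cmd_ok(list(overlays = length(st$overlays)))
}

cmd_render <- function(st, params) {
  map <- need_map(st)
  zoom <- params$zoom %||% map$max_zoom
  img <- render_level(map, zoom, staining = st$staining,
                      overlays = st$overlays,
                      background_mode = params$background)
  if (!is.null(params$out)) {
    write_raster_png(img, params$out)
    cmd_ok(list(path = params$out, side = dim(img)[1L]))
  } else {
    cmd_ok(list(image = img, side = dim(img)[1L]))
  }
}

cmd_enrich <- function(st, params) {
  map <- need_map(st)
  genes <- unlist(params$genes) %||% {
    src <- params$path %||% stopf("enrich needs 'genes' or 'path'")
    parse_data_table(src, "gene_list")$genes
  }
  res <- module_enrichment(map, genes)
  if (!is.null(params$out)) write_enrichment(res, params$out)
  cmd_ok(list(table = res))
}

cmd_list_hugo <- function(st, params) {
  cmd_ok(list(symbols = map_symbols(need_map(st))))
}
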