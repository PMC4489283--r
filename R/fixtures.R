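#' @title Deterministic map and data generators
#' @description
#' Synthetic maps and omics matrices make every pipeline stage testable
#' without any download. Modules are laid out as spatial blocks on a grid
#' so that a planted signal in one module is a contiguous stained region;
#' symbols are synthetic (`GENE0001`, ...); a fraction of symbols is
#' placed twice (aliasing) and one complex shares its members' symbols,
#' exercising the one-symbol-to-many-entities join. All generators are
#' pure functions of their parameters and seed.
#' @name fixtures
NULL

#' Specification for a synthetic grid map
#'
#' @param n_modules number of modules (spatial blocks).
#' @param entities_per_module base entities per module (before aliases).
#' @param canvas_width,canvas_height canvas size in pixels.
#' @param alias_rate fraction of each module's symbols also placed a
#'   second time as an alias entity.
#' @param max_zoom deepest zoom level; entity visibility is staggered
#'   over `[0, max_zoom]` so semantic zoom is exercised.
#' @param seed RNG seed fixing all randomness.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_modules = 5L, entities_per_module = 6L,
                         canvas_width = 800, canvas_height = 600,
                         alias_rate = 0.2, max_zoom = 2L, seed = 1L) {
  if (n_modules < 1L || entities_per_module < 1L) {
    stopf("fixture_spec counts must be >= 1")
  }
  if (alias_rate < 0 || alias_rate > 1) stopf("alias_rate must be in [0, 1]")
  structure(list(
    n_modules = as.integer(n_modules),
    entities_per_module = as.integer(entities_per_module),
    canvas_width = canvas_width, canvas_height = canvas_height,
    alias_rate = alias_rate, max_zoom = as.integer(max_zoom),
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Generate a grid-layout network map
#'
#' Modules occupy rectangular blocks arranged on a grid; entities sit on
#' a jittered sub-grid inside their block. Module 1 additionally gets a
#' complex entity sharing the symbols of its first two members.
#'
#' @param spec a [fixture_spec()].
#' @return a validated `network_map`.
#' @export
make_grid_map <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    nbx <- ceiling(sqrt(spec$n_modules))
    nby <- ceiling(spec$n_modules / nbx)
    bw <- spec$canvas_width / nbx
    bh <- spec$canvas_height / nby
    n_alias <- floor(spec$alias_rate * spec$entities_per_module)
    sub <- ceiling(sqrt(spec$entities_per_module + n_alias))
    if (bw / sub < 8 || bh / sub < 8) {
      stopf("entities exceed canvas capacity: %d per %gx%g block",
            spec$entities_per_module, bw, bh)
    }
    entities <- list()
    modules <- list()
    gene_no <- 0L
    for (mi in seq_len(spec$n_modules)) {
      bx <- (mi - 1L) %% nbx
      by <- (mi - 1L) %/% nbx
      ox <- bx * bw; oy <- by * bh
      member_ids <- character()
      mod_id <- sprintf("module%d", mi)
      mod_syms <- character()
      slots <- expand.grid(ix = seq_len(sub), iy = seq_len(sub))
      slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
      for (ei in seq_len(spec$entities_per_module)) {
        gene_no <- gene_no + 1L
        sym <- sprintf("GENE%04d", gene_no)
        mod_syms <- c(mod_syms, sym)
        pos <- grid_pos(slots[ei, ], bw, bh, sub, ox, oy,
                        spec$canvas_width, spec$canvas_height)
        id <- sprintf("%s_e%d", mod_id, ei)
        entities[[length(entities) + 1L]] <- map_entity(
          id = id, label = sym, class = "protein", hugo = sym,
          x = pos[1L], y = pos[2L], w = min(40, bw / 4), h = min(18, bh / 6),
          modules = mod_id,
          min_zoom = if (ei <= ceiling(spec$entities_per_module / 2)) 0L
                     else min(1L, spec$max_zoom)
        )
        member_ids <- c(member_ids, id)
      }
      if (n_alias > 0L) {
        for (ai in seq_len(n_alias)) {
          pos <- grid_pos(slots[spec$entities_per_module + ai, , drop = FALSE],
                          bw, bh, sub, ox, oy,
                          spec$canvas_width, spec$canvas_height)
          id <- sprintf("%s_alias%d", mod_id, ai)
          entities[[length(entities) + 1L]] <- map_entity(
            id = id, label = mod_syms[ai], class = "protein",
            hugo = mod_syms[ai], x = pos[1L], y = pos[2L],
            w = min(40, bw / 4), h = min(18, bh / 6), modules = mod_id,
            min_zoom = spec$max_zoom
          )
          member_ids <- c(member_ids, id)
        }
      }
      if (mi == 1L && spec$entities_per_module >= 2L) {
        # one complex carrying its two components' symbols
        pos <- c(ox + bw / 2, oy + bh / 2)
        id <- sprintf("%s_complex", mod_id)
        entities[[length(entities) + 1L]] <- map_entity(
          id = id, label = paste(mod_syms[1:2], collapse = ":"),
          class = "complex", hugo = mod_syms[1:2],
          x = min(pos[1L], spec$canvas_width - 1),
          y = min(pos[2L], spec$canvas_height - 1),
          w = min(50, bw / 3), h = min(24, bh / 5),
          modules = mod_id, min_zoom = 0L
        )
        member_ids <- c(member_ids, id)
      }
      modules[[mi]] <- list(id = mod_id, name = sprintf("Module %d", mi),
                            members = member_ids)
    }
    network_map(
      name = sprintf("grid-%dx%d", spec$n_modules, spec$entities_per_module),
      canvas_width = spec$canvas_width, canvas_height = spec$canvas_height,
      max_zoom = spec$max_zoom, entities = entities, modules = modules
    )
  })
}

grid_pos <- function(slot, bw, bh, sub, ox, oy, cw, ch) {
  jx <- stats::runif(1, -bw / (6 * sub), bw / (6 * sub))
  jy <- stats::runif(1, -bh / (6 * sub), bh / (6 * sub))
  x <- ox + (slot$ix - 0.5) * bw / sub + jx
  y <- oy + (slot$iy - 0.5) * bh / sub + jy
  c(min(max(x, 1), cw - 1), min(max(y, 1), ch - 1))
}

# module of a symbol: the module of the first base entity carrying it
symbol_module_map <- function(map) {
  out <- character()
  for (e in map$entities) {
    for (s in e$hugo) {
      if (!s %in% names(out) && length(e$modules)) {
        out[s] <- e$modules[[1L]]
      }
    }
  }
  out
}

#' Generate an expression matrix with planted module effects
#'
#' Values are `baseline + effect + N(0, noise_sd)`, where `effect` is the
#' per-module shift configured for the sample's group. Sample ids are
#' `<group>_<i>`; a matching annotation (factor `group`) is returned
#' alongside the matrix.
#'
#' @param map a `network_map` (genes = its distinct symbols).
#' @param n_per_group named integer vector, group -> sample count.
#' @param module_effects named list: group -> named numeric vector of
#'   per-module shifts (modules absent from the vector shift by 0).
#' @param baseline baseline expression level.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return `list(expression = <tab-delimited text>,
#'   annotation = <tab-delimited text>)`.
#' @export
make_expression_table <- function(map,
                                  n_per_group = c(disease = 5L, control = 5L),
                                  module_effects = list(disease = c(module1 = 2)),
                                  baseline = 7, noise_sd = 0.5, seed = 1L) {
  genes <- map_symbols(map)
  if (length(genes) == 0L) stopf("map has no symbols")
  sym_mod <- symbol_module_map(map)
  groups <- rep(names(n_per_group), times = n_per_group)
  samples <- unlist(lapply(names(n_per_group), function(g)
    sprintf("%s_%d", g, seq_len(n_per_group[[g]]))))
  with_seed(seed, {
    vals <- matrix(stats::rnorm(length(genes) * length(samples),
                                mean = baseline, sd = noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
    for (g in names(module_effects)) {
      eff <- module_effects[[g]]
      for (mod in names(eff)) {
        hit <- !is.na(sym_mod[genes]) & sym_mod[genes] == mod
        vals[hit, groups == g] <- vals[hit, groups == g] + eff[[mod]]
      }
    }
    header <- paste(c("GENE", samples), collapse = "\t")
    body <- vapply(seq_along(genes), function(i)
      paste(c(genes[i], format(vals[i, ], digits = 10, trim = TRUE,
                               scientific = FALSE)), collapse = "\t"), "")
    ann <- c(paste("sample", "group", sep = "\t"),
             paste(samples, groups, sep = "\t"))
    list(expression = paste(c(header, body), collapse = "\n"),
         annotation = paste(ann, collapse = "\n"))
  })
}

#' Generate a mutation matrix with Bernoulli MUT/WT labels
#'
#' @param map a `network_map`.
#' @param frequency per-gene mutation probability: a scalar or a named
#'   vector over the map's symbols (missing names default to the mean).
#' @param n_samples number of samples (`S1 ... Sn`).
#' @param seed RNG seed.
#' @return tab-delimited text with `MUT` / `WT` cells.
#' @export
make_mutation_table <- function(map, frequency = 0.1, n_samples = 10L,
                                seed = 1L) {
  genes <- map_symbols(map)
  if (any(frequency < 0 | frequency > 1)) {
    stopf("mutation frequencies must be in [0, 1]")
  }
  freq <- if (length(frequency) == 1L) {
    stats::setNames(rep(frequency, length(genes)), genes)
  } else {
    f <- stats::setNames(rep(mean(frequency), length(genes)), genes)
    f[names(frequency)] <- frequency
    f
  }
  samples <- sprintf("S%d", seq_len(n_samples))
  with_seed(seed, {
    m <- matrix("WT", nrow = length(genes), ncol = n_samples,
                dimnames = list(genes, samples))
    for (i in seq_along(genes)) {
      m[i, stats::runif(n_samples) < freq[[genes[i]]]] <- "MUT"
    }
    header <- paste(c("GENE", samples), collapse = "\t")
    body <- vapply(seq_along(genes), function(i)
      paste(c(genes[i], m[i, ]), collapse = "\t"), "")
    paste(c(header, body), collapse = "\n")
  })
}
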