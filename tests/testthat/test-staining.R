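test_that("a single site owns the whole canvas", {
  cells <- compute_voronoi(data.frame(entity_id = "a", x = 10, y = 20),
                           c(800, 600))
  expect_length(cells, 1L)
  expect_equal(cells[[1]]$area, 480000)
  expect_false(cells[[1]]$clipped)
})

test_that("two sites split along the perpendicular bisector", {
  cells <- compute_voronoi(
    data.frame(entity_id = c("a", "b"), x = c(1, 3), y = c(1, 1)), c(4, 2))
  expect_equal(vapply(cells, `[[`, 0, "area"), c(4, 4))
  # all of cell a lies at x <= 2, all of b at x >= 2
  expect_true(all(cells[[1]]$polygon[, 1] <= 2 + 1e-9))
  expect_true(all(cells[[2]]$polygon[, 1] >= 2 - 1e-9))
})

test_that("sites outside the canvas and empty site sets are rejected", {
  expect_error(compute_voronoi(data.frame(entity_id = character(),
                                          x = numeric(), y = numeric()),
                               c(10, 10)), "no sites")
  expect_error(compute_voronoi(data.frame(entity_id = "a", x = 11, y = 1),
                               c(10, 10)), "'a'.*outside")
})

test_that("coincident sites merge into one cell owning all entity ids", {
  cells <- compute_voronoi(
    data.frame(entity_id = c("a", "b", "c"), x = c(5, 5, 20), y = c(5, 5, 5)),
    c(30, 10))
  expect_length(cells, 2L)
  expect_setequal(cells[[1]]$entity_ids, c("a", "b"))
})

test_that("raw cells tile the canvas and match the nearest-site oracle", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    sx <- runif(n, 0, 799); sy <- runif(n, 0, 599)
    cells <- compute_voronoi(
      data.frame(entity_id = sprintf("e%d", seq_len(n)), x = sx, y = sy),
      c(800, 600))
    areas <- vapply(cells, `[[`, 0, "area")
    expect_lt(abs(sum(areas) - 480000) / 480000, 1e-6)
    px <- runif(2000, 0, 800); py <- runif(2000, 0, 600)
    near <- nearest_site(px, py, sx, sy)
    for (i in seq_along(cells)) {
      mine <- near == i
      if (!any(mine)) next
      inside <- pathstain:::points_in_convex(cells[[i]]$polygon,
                                             px[mine], py[mine])
      expect_true(all(inside))
    }
  }
})

test_that("an infinite radius leaves cells untouched", {
  cells <- compute_voronoi(
    data.frame(entity_id = c("a", "b"), x = c(100, 300), y = c(100, 100)),
    c(400, 200))
  lim <- limit_cell_extent(cells, radius_factor = Inf)
  expect_equal(vapply(lim, `[[`, 0, "area"),
               vapply(cells, `[[`, 0, "area"))
  expect_false(any(vapply(lim, `[[`, NA, "clipped")))
})

test_that("an absolute radius clips a lone central site to a square", {
  cells <- compute_voronoi(data.frame(entity_id = "a", x = 400, y = 300),
                           c(800, 600))
  lim <- limit_cell_extent(cells, radius = 10)
  expect_equal(lim[[1]]$area, 400)  # 20 x 20 square
  expect_true(lim[[1]]$clipped)
})

test_that("extent limiting is contractive and idempotent", {
  map <- make_grid_map(fixture_spec(seed = 4))
  cells <- compute_voronoi(entity_sites(map),
                           c(map$canvas_width, map$canvas_height))
  lim <- limit_cell_extent(cells, radius_factor = 3)
  expect_lte(sum(vapply(lim, `[[`, 0, "area")),
             map$canvas_width * map$canvas_height + 1e-6)
  for (i in seq_along(cells)) {
    expect_lte(lim[[i]]$area, cells[[i]]$area + 1e-9)
    # every limited vertex stays inside the raw cell
    v <- lim[[i]]$polygon
    if (nrow(v) >= 3) {
      expect_true(all(pathstain:::points_in_convex(cells[[i]]$polygon,
                                                   v[, 1], v[, 2], tol = 1e-6)))
    }
  }
  lim2 <- limit_cell_extent(lim, radius_factor = 3)
  expect_equal(vapply(lim2, `[[`, 0, "area"),
               vapply(lim, `[[`, 0, "area"), tolerance = 1e-9)
  expect_error(limit_cell_extent(cells, radius_factor = 0), "> 0")
})

test_that("staining without data leaves every cell unstained", {
  map <- tiny_map()
  layer <- build_staining_layer(map, c(NOTONMAP = 1))
  expect_true(all(is.na(layer$fill)))
  expect_equal(length(layer$fill), length(layer$cells))
})

test_that("the minimum value stains its territory with the low (green) anchor", {
  map <- tiny_map()
  vals <- c(EGFR = 1, MDM2 = 5, TP53 = 9)
  layer <- build_staining_layer(map, vals)
  egfr_cell <- which(vapply(layer$cells,
                            function(c) "egfr" %in% c$entity_ids, NA))
  expect_identical(layer$fill[egfr_cell], "#00FF00FF")
})

test_that("alias territories of one symbol stain identically", {
  map <- make_grid_map(fixture_spec(seed = 8, alias_rate = 0.5))
  idx <- symbol_index(map)
  dup_sym <- names(idx)[vapply(idx, length, 0L) == 2][1]
  vals <- stats::setNames(seq_along(map_symbols(map)), map_symbols(map))
  layer <- build_staining_layer(map, vals)
  ids <- idx[[dup_sym]]
  fills <- vapply(ids, function(id) {
    layer$fill[which(vapply(layer$cells,
                            function(c) id %in% c$entity_ids, NA))[1]]
  }, "")
  expect_identical(fills[[1]], fills[[2]])
})

test_that("swapping two genes' values swaps their cell colors exactly", {
  map <- tiny_map()
  vals <- c(TP53 = 1, MDM2 = 5, EGFR = 9)
  scale <- gradient_scale(c(1, 9), c("#00FF00", "#FF0000"))
  cell_of <- function(layer, id) {
    layer$fill[which(vapply(layer$cells,
                            function(c) identical(c$entity_ids, id), NA))]
  }
  l1 <- build_staining_layer(map, vals, scale = scale)
  swapped <- c(TP53 = 9, MDM2 = 5, EGFR = 1)
  l2 <- build_staining_layer(map, swapped, scale = scale)
  expect_identical(cell_of(l1, "p53"), cell_of(l2, "egfr"))
  expect_identical(cell_of(l1, "egfr"), cell_of(l2, "p53"))
  expect_identical(cell_of(l1, "mdm2"), cell_of(l2, "mdm2"))
})

test_that("staining layers export as SVG polygons", {
  map <- tiny_map()
  layer <- build_staining_layer(map, c(TP53 = 1, MDM2 = 2))
  svg <- staining_to_svg(layer)
  expect_match(svg, "^<svg")
  expect_equal(lengths(regmatches(svg, gregexpr("<polygon", svg))),
               length(layer$cells))
})
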