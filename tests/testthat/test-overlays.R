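test_that("a symbol present free and in a complex yields two markers", {
  res <- build_markers(tiny_map(), c("TP53"))
  expect_length(res$markers, 2L)
  expect_setequal(vapply(res$markers, `[[`, "", "entity_id"),
                  c("p53", "cplx"))
  # markers anchor at entity positions
  for (mk in res$markers) {
    e <- pathstain:::find_entity(tiny_map(), mk$entity_id)
    expect_equal(c(mk$x, mk$y), c(e$x, e$y))
  }
})

test_that("unmatched symbols are reported, not dropped", {
  res <- build_markers(tiny_map(), c("NOPE1", "NOPE2"))
  expect_length(res$markers, 0L)
  expect_setequal(res$unmatched, c("NOPE1", "NOPE2"))
})

test_that("marker count equals the sum of symbol-index hits", {
  map <- make_grid_map(fixture_spec(seed = 3, alias_rate = 0.4))
  syms <- map_symbols(map)[1:8]
  res <- build_markers(map, syms)
  idx <- symbol_index(map)
  expect_length(res$markers, sum(lengths(idx[syms])))
})

test_that("heatmap grids have one row per table, one column per selection", {
  map <- tiny_map()
  expr <- parse_data_table(tiny_expression(), "mrna_expression")
  mut <- parse_data_table(tiny_mutation(), "mutation")
  hv <- build_heatmap(map, "p53", list(expr = expr), list("S1"))
  expect_identical(dim(hv$values), c(1L, 1L))
  ann <- parse_sample_annotation(tiny_annotation())
  gs <- build_groups(ann, "disease")
  h2 <- build_heatmap(map, "p53", list(expr = expr, mut = mut),
                      list(gs[[1]], gs[[2]], "S2"))
  expect_identical(dim(h2$values), c(2L, 3L))
  expect_identical(rownames(h2$values), c("expr", "mut"))
})

test_that("heatmap cells equal value_to_color of the summarized values", {
  map <- tiny_map()
  expr <- parse_data_table(tiny_expression(), "mrna_expression")
  scale <- gradient_scale(c(-2, 0, 3), c("#00FF00", "#FFFFFF", "#FF0000"))
  ann <- parse_sample_annotation(tiny_annotation())
  gs <- build_groups(ann, "disease")
  h <- build_heatmap(map, "mdm2", list(expr = expr), list(gs[[1]], "S3"),
                     scales = list(expr = scale))
  # group AD = mean(-1.5, NA) = -1.5 ; sample S3 = 0.5
  expect_equal(unname(h$values[1, ]), c(-1.5, 0.5))
  expect_identical(unname(h$colors[1, ]),
                   value_to_color(scale, c(-1.5, 0.5)))
})

test_that("an entity with no data in any table signals an empty overlay", {
  map <- tiny_map()
  expr <- parse_data_table(tiny_expression(), "mrna_expression")
  expect_null(build_heatmap(map, "death", list(expr = expr), list("S1")))
})

test_that("bar heights are proportional to values within one table", {
  map <- tiny_map()
  expr <- parse_data_table(tiny_expression(), "mrna_expression")
  bp <- build_barplot(map, "p53", expr, list("S1", "S2", "S3"),
                      max_height_px = 30)
  h <- bp$bars$height_px
  v <- bp$bars$value
  expect_equal(h[1] / h[2], v[1] / v[2])
  expect_equal(h[2] / h[3], v[2] / v[3])
  # zero value -> zero height; negative draws downward (negative height)
  tab0 <- parse_data_table("GENE\tS1\tS2\nTP53\t0\t-2", "mrna_expression")
  bp0 <- build_barplot(map, "p53", tab0, list("S1", "S2"))
  expect_equal(bp0$bars$height_px[1], 0)
  expect_lt(bp0$bars$height_px[2], 0)
})

test_that("barplot normalization uses the per-table global maximum", {
  map <- tiny_map()
  expr <- parse_data_table(tiny_expression(), "mrna_expression")
  bp1 <- build_barplot(map, "p53", expr, list("S3"), max_height_px = 40)
  # global max |value| over the whole table is 3.0 (TP53, S3)
  expect_equal(bp1$bars$height_px, 40)
  bp2 <- build_barplot(map, "mdm2", expr, list("S3"), max_height_px = 40)
  expect_equal(bp2$bars$height_px, 0.5 / 3 * 40)
})

test_that("exactly five glyphs fit on one entity", {
  ov <- glyph_overlay(tiny_map(), "p53")
  shapes <- c("triangle", "square", "circle", "diamond", "hexagon")
  for (s in shapes) ov <- attach_glyph(ov, shape = s)
  expect_length(ov$glyphs, 5L)
  expect_identical(vapply(ov$glyphs, `[[`, 0L, "slot"), 1:5)
  expect_error(attach_glyph(ov, shape = "circle"), "maximum")
})

test_that("glyph channels can come from different data tables", {
  map <- tiny_map()
  cn <- parse_data_table("GENE\tS1\nTP53\t2", "copynumber_discrete")
  expr <- parse_data_table(tiny_expression(), "mrna_expression")
  # shape driven by the copy-number state, color by expression
  state <- summarize_group(cn, "S1")[["TP53"]]
  shape <- if (state >= 1) "triangle" else if (state <= -1) "diamond" else "square"
  scale <- default_expression_scale(expr$values)
  col <- value_to_color(scale, expr$values["TP53", "S1"])
  ov <- attach_glyph(glyph_overlay(map, "p53"), shape = shape, color = col)
  expect_identical(ov$glyphs[[1]]$shape, "triangle")
  expect_identical(ov$glyphs[[1]]$color, col)
})

test_that("glyph size maps values affinely with clamping", {
  expect_equal(glyph_size_from_value(1, 0, 1, 4, 20), 20)
  expect_equal(glyph_size_from_value(0, 0, 1, 4, 20), 4)
  expect_equal(glyph_size_from_value(0.5, 0, 1, 4, 20), 12)
  expect_equal(glyph_size_from_value(2, 0, 1, 4, 20), 20)   # clamp high
  expect_equal(glyph_size_from_value(-1, 0, 1, 4, 20), 4)   # clamp low
  expect_error(glyph_size_from_value(0.5, 1, 1, 4, 20), "vmin < vmax")
})

test_that("overlay sets serialize to JSON layer files", {
  map <- tiny_map()
  ov <- attach_glyph(glyph_overlay(map, "p53"))
  mk <- build_markers(map, "EGFR")$markers
  txt <- overlays_to_json(c(list(ov), mk))
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_length(parsed, 2L)
  expect_identical(parsed[[1]]$kind, "glyph_overlay")
  expect_identical(parsed[[2]]$kind, "marker")
})
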