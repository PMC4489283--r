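---
title: "Visualizing omics data on pathway maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing omics data on pathway maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathstain)
```

# The problem

Large molecular network maps — cell-cycle maps, disease maps with
thousands of positioned species — are useful as a *support* for data:
a transcriptome, copy-number calls or mutation lists projected onto the
map reveal which parts of the biology a sample engages. `pathstain`
implements that projection pipeline end to end: a positioned map model,
typed omics ingestion, sample-group summarization, four entity-anchored
overlay kinds plus the Voronoi **map staining** background, slippy-map
tile rendering with semantic zoom, and hypergeometric module enrichment.

# The map model

A map is a pixel canvas (origin top-left, y down, matching image and
tile conventions) with positioned entities. Each entity carries HUGO
gene-symbol aliases used to join data rows to it: a complex lists the
symbols of its components, so the same symbol can legitimately resolve
to several entities (the free protein and every complex containing it).
Symbols are canonicalized to uppercase with whitespace stripped, and
matching is case-insensitive — HUGO symbols are conventionally
uppercase while user files vary. Duplicate symbols within one entity
are dropped silently.

Maps travel as a self-contained JSON descriptor rather than a pathway
interchange format: the descriptor holds exactly the information the
five visualization modes need (positions, classes, aliases, modules,
zoom visibility) and makes the whole pipeline testable from generated
fixtures. `save_map()` is a canonical writer (fixed key order, fixed
indentation, full precision), so `save_map(load_map(d))` reproduces a
canonical descriptor byte for byte — the property the determinism tests
lean on.

Semantic zoom is modeled with one integer per entity, `min_zoom`: the
entity is drawn at every zoom at or below the map's `max_zoom` and at
or above its own `min_zoom`, so the visible set grows monotonically as
the user zooms in. Reaction edges are deliberately out of scope:
entities and positions suffice for all five representations.

# Data types and group summarization

Seven biological input types map onto four internal representations,
and the representation — not the file — decides which visualizations
and which group-summarization rules apply:

| data type              | internal representation |
|------------------------|-------------------------|
| mRNA expression        | continuous              |
| microRNA expression    | continuous              |
| protein expression     | continuous              |
| discrete copy number   | discrete ordered        |
| continuous copy number | continuous              |
| mutation               | discrete unordered      |
| gene list              | set                     |

Matrices are tab-delimited text, genes in rows (HUGO symbols in the
first column), samples in columns; `""`, `"NA"`, `"NaN"` and `"N/A"`
(case-insensitive) mark missing cells. Duplicate gene rows are a hard
error by default with an opt-in mean aggregation
(`aggregate_duplicates = "mean"`): silent averaging hides upstream
identifier mistakes, so it must be requested.

Sample annotations assign each sample a level per factor; one group per
non-missing level. Summarization per representation:

* **continuous** — arithmetic mean over non-missing members (the
  default; median, min and max selectable per call);
* **discrete unordered (mutation)** — "at least one member of the
  group is mutated". A cell counts as mutated when it is non-missing
  and not `WT`/`0` (case-insensitive); mutation files in the wild carry
  free-form protein-change strings, so any other non-empty label is
  treated as an event;
* **discrete ordered (copy number)** — no canonical rule exists for
  this representation, so the package takes the modal state and breaks
  frequency ties toward the state of largest magnitude; a −2/+2 tie
  thus resolves to an aberrant call rather than inventing a neutral
  one;
* **set** — union of memberships.

A gene whose members are all missing stays missing through every rule,
and column order never affects any summary (a tested invariant).

# Map staining

Map staining colors the background *territory* of each entity by its
value, making whole-omics trends legible at the top zoom level where
individual entities are too small to read. The territory of an entity
is its Voronoi cell — the convex polygon of canvas points closer to it
than to any other entity — built here by clipping the canvas rectangle
with the perpendicular-bisector half-plane against every other site
(Sutherland–Hodgman, O(n²) over sites, exact intersection points).
Before post-processing the cells tile the canvas exactly; the area
conservation check in the tests runs at 10⁻⁶ relative tolerance and the
polygons are verified against a brute-force nearest-site oracle at 10⁴
random probe points per site set.

Three degenerate-input and post-processing rules are the package's own
choices where no canonical rule exists:

* **Large-territory limiting.** Border entities own unbounded-looking
  cells in sparse map regions. Each cell is intersected with the
  axis-aligned square of half-width `R` centered on its site, with
  `R = radius_factor ×` (median nearest-neighbor distance among sites)
  and `radius_factor = 3` by default. The median nearest-neighbor
  distance makes the rule scale-free per map; the operation is
  contractive and idempotent (tested), and `radius_factor = Inf`
  disables it. An absolute pixel radius can be given instead.
* **Aliases.** Every placement of a symbol is its own Voronoi site
  carrying the same value, so both copies of an aliased gene stain
  identically (tested); merging aliases into one site would tear a
  hole in the tessellation where the second copy sits.
* **Coincident sites** merge into a single cell owning all their
  entity ids; the cell's value is the mean over those entities.

An entity's stain value is the mean over its valued symbols (relevant
for complexes); entities with no value stay unstained and show the
neutral background, so absence of data is visually distinct from any
mid-scale value. When staining is active the map itself is drawn in
black and white so entity decoration does not mix with territory color.

# Color scales

* **Continuous (expression)**: a three-anchor gradient, data minimum →
  green, midpoint → white, maximum → red. The midpoint defaults to the
  median of the mapped values — robust to a single outlier compressing
  the visible range — and all anchors are overridable via
  `gradient_scale()`.
* **Discrete ordered (copy number)**: threshold bands — blue for −1
  and lower (loss), white for 0, yellow for +1 and higher
  (amplification). Band bounds are inclusive; an exhaustive integer
  sweep from −5 to 5 pins the thresholds in the tests.
* **Discrete unordered**: an explicit label → color palette; unknown
  labels are an error naming the label.
* Mutated genes conventionally get a **cyan triangle** glyph
  (`default_mutation_glyph()`).

# Overlays

Markers place one pictogram per matched entity occurrence — a symbol
found as a free protein and inside a complex yields two markers — and
report unmatched symbols. Heatmap overlays are rectangular grids, one
row per data table and one column per selected sample or group, each
cell colored through its table's scale; an entity with no data in any
table signals an empty overlay so callers can skip it. Barplot heights
are normalized by the *per-table* global maximum absolute value rather
than per entity, so two bars on opposite ends of the map are
comparable; negative values draw downward from the baseline. Glyphs
are capped at five per entity in five fixed slots around the bounding
box (four corners plus top-center); the shape, color and size channels
of each glyph can be resolved from different tables (e.g. shape from
copy-number state, color from expression, size from mutation frequency
via the clamped affine map `glyph_size_from_value()`).

# Rendering and tiles

The world at zoom `z` is a `256·2^z` pixel square of 256-px tiles
(`4^z` tiles per level, addressed `z/x/y.png`). The canvas sits at
native scale in the top-left of the deepest level's world square and is
padded with a neutral background. Every level is drawn at native
resolution with that level's visible entity set and reduced by exact
block averaging; block means compose across factors of two, so
stitching level `z` and halving it reproduces level `z−1` up to
semantic content differences and 8-bit PNG quantization (measured in
the tests at well under a mean per-channel error of 2/255). Staining is
rasterized by per-pixel nearest site — the exact Voronoi partition —
restricted to each cell's extent square, rather than by scan-converting
polygons, which removes a whole class of edge-pixel artifacts.
Rendering is deterministic: the same inputs produce bit-identical
arrays and PNGs.

# Module enrichment

The functional-analysis statistic is the upper-tail hypergeometric
probability of the observed overlap between an uploaded gene list and
each module. Three design points the package had to fix itself:

* **Universe** = distinct symbols on the map, not the genome: the test
  asks "which module *of this map* is enriched", and a genome-wide
  universe would reward modules merely for being on the map. Uploaded
  symbols absent from the map are dropped from the list size `n`.
* **Aliases** count once: module size `K` and overlap `k` are over
  distinct symbols, so placing a gene twice does not double its
  evidence.
* **Multiple testing**: Benjamini–Hochberg across the map's modules is
  emitted as `q_value` alongside the raw `p_value`.

The tail sum is accumulated in log space (`lchoose` + log-sum-exp) and
is tested against exhaustive enumeration of all draws for every
parameter combination up to a universe of 12, and against
`stats::phyper` on a broader sweep.

# Sessions, commands, CLI

Automation goes through a session engine: `create_session()` returns a
128-bit random token; `execute_command()` takes JSON
(`{"action": ..., "params": {...}}`) and dispatches to the library
(`load_map`, `import_datatable`, `define_groups`, `set_staining`,
`add_overlay`, `render`, `enrich`, `list_hugo`), with 404/400-style
error responses. Sessions are isolated; identical command sequences
replayed in fresh sessions produce bit-identical artifacts (tested).
The batch CLI (`inst/cli/pathstain.R`) appends each subcommand as a
JSON command to a per-session log and replays the log through the
engine, so CLI and programmatic use are the same code path by
construction. The engine is in-process: the JSON command vocabulary,
not a transport, is the binding surface, and no HTTP listener ships
with the package.

# The fixture generators

`make_grid_map()` lays modules out as rectangular blocks on a grid with
entities on a jittered sub-grid inside each block, so a planted module
signal is a spatially contiguous stained region whose mean color can be
measured per block. Symbols are synthetic (`GENE0001`, ...); an
`alias_rate` fraction of each module's symbols is placed twice, one
complex shares its two components' symbols, and `min_zoom` is staggered
so semantic zoom is exercised. `make_expression_table()` draws
`baseline + module effect + N(0, sd)` with sample ids encoding their
group, and `make_mutation_table()` draws Bernoulli `MUT`/`WT` labels.
All generators are pure functions of their parameters and seed and
restore the caller's RNG state.

The default planted-signal condition used in the recovery tests is a
5-module, 6-entities-per-module map (alias rate 0.2) with one module
up-shifted by 2.0 on a noise standard deviation of 0.5, five disease
and five control samples — a strong but realistic group effect (four
noise standard deviations on a group mean of five). What these
fixtures deliberately do **not** emulate: realistic pathway topology,
correlated gene-gene noise, real symbol vocabularies, missing-data
structure, or maps with hundreds of thousands of entities. Passing the
recovery tests therefore demonstrates that the pipeline is faithful —
values survive ingestion, summarization, coloring and tessellation
unchanged — not that the visualization will detect weak signals in
noisy real cohorts.

# Numerical choices and problem sizes

Geometry uses a relative tolerance of about 10⁻⁹ when classifying
vertices against clip half-planes and 10⁻⁷ when testing point-polygon
membership; intersection points themselves are computed exactly from
the edge parametrization. Area conservation is asserted at 10⁻⁶
relative error. The test suite runs Voronoi oracle checks on 20 random
site sets of up to 200 sites with 10⁴ probes each, exhaustive
hypergeometric enumeration to a universe of 12, and tile-stitching
checks to zoom 3 (85 tiles); the full suite and the acceptance script
each complete in about a minute on a single core.

# Known limitations

* Voronoi cells use unweighted Euclidean distance; entity bounding
  boxes do not influence territory shape (no power/weighted diagrams).
* The renderer is a flat rasterizer without anti-aliasing; glyph and
  marker edges are hard.
* The descriptor model has no reaction edges, so edge-aware layouts or
  edge rendering are out of reach by design.
* `discrete_ordered` summarization (mode, magnitude tie-break) is a
  package convention, not a community standard; override by summarizing
  upstream if a different rule is needed.
* The command engine holds sessions in process memory; nothing is
  persisted except what `render`/`tiles`/`enrich` write to disk.
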