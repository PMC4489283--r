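# Hand-built micro-map: TP53 as a free protein and inside a TP53:MDM2
# complex, one phenotype without symbols, two modules.
tiny_map <- function() {
  network_map(
    name = "tiny", canvas_width = 400, canvas_height = 300, max_zoom = 2,
    entities = list(
      map_entity("p53", label = "TP53", hugo = "TP53",
                 x = 100, y = 100, modules = "apoptosis"),
      map_entity("mdm2", label = "MDM2", hugo = "MDM2",
                 x = 200, y = 80, modules = "apoptosis"),
      map_entity("cplx", label = "TP53:MDM2", class = "complex",
                 hugo = c("TP53", "MDM2"), x = 150, y = 150,
                 modules = "apoptosis", min_zoom = 1),
      map_entity("egfr", label = "EGFR", hugo = "EGFR",
                 x = 320, y = 220, modules = "growth", min_zoom = 2),
      map_entity("death", label = "cell death", class = "phenotype",
                 hugo = character(), x = 50, y = 250, modules = "apoptosis")
    ),
    modules = list(
      list(id = "apoptosis", name = "Apoptosis",
           members = c("p53", "mdm2", "cplx", "death")),
      list(id = "growth", name = "Growth", members = "egfr")
    )
  )
}

# tab-delimited expression text, 2 genes x 3 samples
tiny_expression <- function() {
  paste(
    "GENE\tS1\tS2\tS3",
    "TP53\t1.0\t2.0\t3.0",
    "MDM2\t-1.5\tNA\t0.5",
    sep = "\n"
  )
}

tiny_mutation <- function() {
  paste(
    "GENE\tS1\tS2\tS3",
    "TP53\tWT\tp.R175H\tWT",
    "MDM2\tWT\tWT\tWT",
    sep = "\n"
  )
}

tiny_annotation <- function() {
  paste(
    "sample\tdisease\tbatch",
    "S1\tAD\tb1",
    "S2\tAD\tb2",
    "S3\tCTRL\tb1",
    sep = "\n"
  )
}

# brute-force nearest-site index for probe points
nearest_site <- function(px, py, sx, sy) {
  vapply(seq_along(px), function(i) {
    which.min((sx - px[i])^2 + (sy - py[i])^2)
  }, 0L)
}

entity_sites <- function(map) {
  data.frame(
    entity_id = vapply(map$entities, `[[`, "", "id"),
    x = vapply(map$entities, `[[`, 0, "x"),
    y = vapply(map$entities, `[[`, 0, "y"),
    stringsAsFactors = FALSE
  )
}

# exhaustive hypergeometric tail by enumerating all n-subsets of 1:N
enum_hypergeom_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are "marked"
  sum(hits >= k) / ncol(draws)
}
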