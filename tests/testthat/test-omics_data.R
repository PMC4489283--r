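test_that("every biological data type maps to its internal representation", {
  expected <- c(
    mrna_expression       = "continuous",
    microrna_expression   = "continuous",
    protein_expression    = "continuous",
    copynumber_discrete   = "discrete_ordered",
    copynumber_continuous = "continuous",
    mutation              = "discrete_unordered",
    gene_list             = "set"
  )
  for (dt in names(expected)) {
    expect_identical(internal_repr_of(dt), unname(expected[dt]))
  }
  expect_error(internal_repr_of("methylation"), "accepted types")
})

test_that("expression text parses into a typed continuous table", {
  tab <- parse_data_table(tiny_expression(), "mrna_expression")
  expect_identical(tab$internal_repr, "continuous")
  expect_identical(tab$genes, c("TP53", "MDM2"))
  expect_identical(tab$samples, c("S1", "S2", "S3"))
  expect_equal(tab$values["TP53", "S2"], 2.0)
  expect_true(is.na(tab$values["MDM2", "S2"]))  # "NA" cell is missing
})

test_that("gene-list files become single-column set tables", {
  tab <- parse_data_table("TP53\nmdm2\nEGFR\n", "gene_list")
  expect_identical(tab$internal_repr, "set")
  expect_identical(tab$genes, c("TP53", "MDM2", "EGFR"))
  expect_identical(dim(tab$values), c(3L, 1L))
  # header form accepted too
  tab2 <- parse_data_table("GENE\nTP53\nMDM2\nEGFR", "gene_list")
  expect_identical(tab2$genes, tab$genes)
})

test_that("parse errors carry the location of the defect", {
  expect_error(
    parse_data_table("GENE\tS1\nTP53\t1\nTP53\t2", "mrna_expression"),
    "duplicate gene row 'TP53'")
  expect_error(
    parse_data_table("GENE\tS1\tS2\nTP53\t1", "mrna_expression"),
    "line 2")
  expect_error(
    parse_data_table("GENE\tS1\nTP53\tlots", "mrna_expression"),
    "TP53.*S1|S1.*TP53")
  expect_error(
    parse_data_table("GENE\tS1\nTP53\t0.5", "copynumber_discrete"),
    "non-integer")
})

test_that("duplicate gene rows can be mean-aggregated on request", {
  tab <- parse_data_table("GENE\tS1\tS2\nTP53\t1\t4\nTP53\t3\tNA",
                          "mrna_expression", aggregate_duplicates = "mean")
  expect_equal(unname(tab$values["TP53", ]), c(2, 4))
})

test_that("groups partition the samples that have a factor level", {
  ann <- parse_sample_annotation(tiny_annotation())
  gs <- build_groups(ann, "disease")
  expect_length(gs, 2L)
  expect_identical(gs[[1]]$group_id, "disease:AD")
  expect_setequal(gs[[1]]$members, c("S1", "S2"))
  expect_identical(gs[[2]]$members, "S3")
  # a second factor is built independently
  gb <- build_groups(ann, "batch")
  expect_setequal(vapply(gb, `[[`, "", "level"), c("b1", "b2"))
  expect_error(build_groups(ann, "nope"), "disease")
})

test_that("an all-NA factor yields no groups", {
  ann <- parse_sample_annotation("sample\tf\nS1\tNA\nS2\tNA")
  expect_length(build_groups(ann, "f"), 0L)
})

test_that("continuous groups average over non-missing members", {
  tab <- parse_data_table(tiny_expression(), "mrna_expression")
  g <- structure(list(group_id = "all", members = c("S1", "S2", "S3")),
                 class = "sample_group")
  s <- summarize_group(tab, g)
  expect_equal(unname(s["TP53"]), 2.0)          # (1+2+3)/3
  expect_equal(unname(s["MDM2"]), (-1.5 + 0.5) / 2)  # NA excluded
  expect_equal(unname(summarize_group(tab, g, method = "median")["TP53"]), 2)
  expect_equal(unname(summarize_group(tab, g, method = "max")["TP53"]), 3)
})

test_that("mutation groups flag 'at least one member mutated'", {
  tab <- parse_data_table(tiny_mutation(), "mutation")
  g <- structure(list(group_id = "all", members = c("S1", "S2", "S3")),
                 class = "sample_group")
  s <- summarize_group(tab, g)
  expect_true(s[["TP53"]])    # WT, p.R175H, WT -> mutated
  expect_false(s[["MDM2"]])   # all WT
})

test_that("a single-member group returns that member's value unchanged", {
  expr <- parse_data_table(tiny_expression(), "mrna_expression")
  mut <- parse_data_table(tiny_mutation(), "mutation")
  expect_equal(summarize_group(expr, "S1"),
               stats::setNames(expr$values[, "S1"], expr$genes))
  expect_identical(unname(summarize_group(mut, "S2")), c(TRUE, FALSE))
})

test_that("discrete-ordered groups take the mode, ties to largest magnitude", {
  tab <- parse_data_table(
    "GENE\ta\tb\tc\td\nG1\t-2\t-2\t1\t1\nG2\t0\t0\t0\t2\nG3\tNA\tNA\tNA\tNA",
    "copynumber_discrete")
  s <- summarize_group(tab, c("a", "b", "c", "d"))
  expect_equal(unname(s["G1"]), -2)  # tie {-2, 1} -> larger magnitude
  expect_equal(unname(s["G2"]), 0)
  expect_true(is.na(s["G3"]))
})

test_that("group summaries match per-cell recomputation and ignore column order", {
  set.seed(42)
  for (rep in 1:5) {
    ng <- sample(3:8, 1); ns <- sample(4:9, 1)
    vals <- matrix(rnorm(ng * ns), ng)
    vals[sample(length(vals), ng)] <- NA
    genes <- sprintf("G%d", seq_len(ng)); samples <- sprintf("S%d", seq_len(ns))
    txt <- paste(c(paste(c("GENE", samples), collapse = "\t"),
                   vapply(seq_len(ng), function(i)
                     paste(c(genes[i], vals[i, ]), collapse = "\t"), "")),
                 collapse = "\n")
    tab <- parse_data_table(txt, "mrna_expression")
    members <- sample(samples, 3)
    got <- summarize_group(tab, members)
    # independent brute-force mean per gene
    want <- vapply(seq_len(ng), function(i) {
      v <- vals[i, match(members, samples)]
      if (all(is.na(v))) NA_real_ else sum(v[!is.na(v)]) / sum(!is.na(v))
    }, 0)
    expect_equal(unname(got), want)
    # permuting sample columns changes nothing
    perm <- sample(ns)
    txt2 <- paste(c(paste(c("GENE", samples[perm]), collapse = "\t"),
                    vapply(seq_len(ng), function(i)
                      paste(c(genes[i], vals[i, perm]), collapse = "\t"), "")),
                  collapse = "\n")
    expect_equal(summarize_group(parse_data_table(txt2, "mrna_expression"),
                                 members), got)
  }
})

test_that("mutation labels beyond WT/0/missing count as mutated", {
  expect_identical(is_mutated(c("WT", "wt", "0", "", "NA", "MUT", "p.G12D")),
                   c(FALSE, FALSE, FALSE, NA, NA, TRUE, TRUE))
})
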