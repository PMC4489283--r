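#' @title Typed omics data tables
#' @description
#' Omics matrices arrive as tab-delimited text with genes in rows (first
#' column HUGO symbols) and samples in columns. Each biological data type
#' is bound to one of four internal representations which determines the
#' visualizations that apply and how sample groups are summarized:
#'
#' | data type              | internal representation |
#' |------------------------|-------------------------|
#' | mrna_expression        | continuous              |
#' | microrna_expression    | continuous              |
#' | protein_expression     | continuous              |
#' | copynumber_discrete    | discrete_ordered        |
#' | copynumber_continuous  | continuous              |
#' | mutation               | discrete_unordered      |
#' | gene_list              | set                     |
#' @name omics_data
NULL

.repr_map <- c(
  mrna_expression       = "continuous",
  microrna_expression   = "continuous",
  protein_expression    = "continuous",
  copynumber_discrete   = "discrete_ordered",
  copynumber_continuous = "continuous",
  mutation              = "discrete_unordered",
  gene_list             = "set"
)

.missing_markers <- c("", "na", "nan", "n/a")

is_missing_cell <- function(x) {
  is.na(x) | tolower(trimws(x)) %in% .missing_markers
}

#' Internal representation of a biological data type
#'
#' @param data_type one of `mrna_expression`, `microrna_expression`,
#'   `protein_expression`, `copynumber_discrete`, `copynumber_continuous`,
#'   `mutation`, `gene_list`.
#' @return one of `"continuous"`, `"discrete_ordered"`,
#'   `"discrete_unordered"`, `"set"`.
#' @export
internal_repr_of <- function(data_type) {
  if (length(data_type) != 1L || !data_type %in% names(.repr_map)) {
    stopf("unknown data type '%s'; accepted types: %s",
          paste(data_type, collapse = ","),
          paste(names(.repr_map), collapse = ", "))
  }
  unname(.repr_map[[data_type]])
}

#' Mutation-status predicate
#'
#' Mutation tables carry free-form labels. Any non-missing label other than
#' `"WT"` (case-insensitive) or `"0"` counts as mutated.
#'
#' @param x character vector of mutation-cell labels.
#' @return logical vector; `NA` where the cell is missing.
#' @export
is_mutated <- function(x) {
  out <- !(toupper(trimws(x)) %in% c("WT", "0"))
  out[is_missing_cell(x)] <- NA
  out
}

split_tsv_lines <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- sub("\r$", "", lines)
  lines[seq_len(max(which(nzchar(lines)), 0L))]
}

#' Parse a tab-delimited omics matrix
#'
#' Expects a header row (gene column label + sample ids) and one row per
#' gene with the HUGO symbol in the first column. Gene lists (data type
#' `gene_list`) are one symbol per line, with or without a header, and
#' become a single-column set-representation table. Cells equal to
#' `""`, `"NA"`, `"NaN"` or `"N/A"` (case-insensitive) are missing.
#'
#' @param x path to the file, or the text itself.
#' @param data_type biological data type; see [internal_repr_of()].
#' @param name table name (defaults to the data type).
#' @param aggregate_duplicates how to treat duplicate gene rows:
#'   `"error"` (default) or `"mean"` (numeric representations only).
#' @return an `omics_table` with fields `name`, `data_type`,
#'   `internal_repr`, `genes`, `samples` and `values` (numeric matrix for
#'   continuous/discrete_ordered, character for discrete_unordered,
#'   logical for set; `NA` marks missing cells).
#' @export
parse_data_table <- function(x, data_type, name = data_type,
                             aggregate_duplicates = c("error", "mean")) {
  repr <- internal_repr_of(data_type)
  aggregate_duplicates <- match.arg(aggregate_duplicates)
  txt <- read_text_arg(x, "data table")
  lines <- split_tsv_lines(txt)
  if (length(lines) == 0L) stopf("empty data table '%s'", name)

  if (repr == "set") {
    first <- canon_symbol(strsplit(lines[1L], "\t")[[1]][1L])
    if (first %in% c("GENE", "SYMBOL", "HUGO", "GENES")) lines <- lines[-1L]
    genes <- canon_symbol(vapply(strsplit(lines, "\t"), `[[`, "", 1L))
    genes <- unique(genes[nzchar(genes)])
    values <- matrix(TRUE, nrow = length(genes), ncol = 1L,
                     dimnames = list(genes, "LIST"))
    return(new_omics_table(name, data_type, repr, genes, "LIST", values))
  }

  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expect <- length(cells[[1L]])
  widths <- lengths(cells)
  if (any(widths != ncol_expect)) {
    bad <- which(widths != ncol_expect)[1L]
    stopf("ragged row in table '%s': line %d has %d fields, expected %d",
          name, bad, widths[bad], ncol_expect)
  }
  if (ncol_expect < 2L) stopf("table '%s' has no sample columns", name)
  samples <- cells[[1L]][-1L]
  if (anyDuplicated(samples)) {
    stopf("duplicate sample id '%s' in table '%s'",
          samples[duplicated(samples)][1L], name)
  }
  body <- cells[-1L]
  genes <- canon_symbol(vapply(body, `[[`, "", 1L))
  raw <- matrix(unlist(lapply(body, `[`, -1L)), nrow = length(body),
                byrow = TRUE, dimnames = list(genes, samples))

  if (anyDuplicated(genes)) {
    if (aggregate_duplicates == "error" || repr == "discrete_unordered") {
      stopf("duplicate gene row '%s' in table '%s'",
            genes[duplicated(genes)][1L], name)
    }
  }

  if (repr %in% c("continuous", "discrete_ordered")) {
    vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = dimnames(raw)))
    vals[is_missing_cell(raw)] <- NA_real_
    bad <- which(is.na(vals) & !is_missing_cell(raw), arr.ind = TRUE)
    if (nrow(bad)) {
      stopf("non-numeric cell '%s' in table '%s' at (gene %s, sample %s)",
            raw[bad[1L, , drop = FALSE]], name,
            genes[bad[1L, 1L]], samples[bad[1L, 2L]])
    }
    if (repr == "discrete_ordered") {
      frac <- vals[!is.na(vals)]
      if (any(frac != round(frac))) {
        stopf("table '%s' is discrete ordered but contains non-integer values",
              name)
      }
    }
    if (anyDuplicated(genes)) {  # aggregate_duplicates == "mean"
      agg <- rowsum(vals, group = genes, na.rm = TRUE)
      cnt <- rowsum((!is.na(vals)) + 0, group = genes)
      vals <- agg / cnt
      vals[cnt == 0] <- NA_real_
      genes <- rownames(vals)
      if (repr == "discrete_ordered") vals <- round(vals)
      dimnames(vals) <- list(genes, samples)
    }
  } else {  # discrete_unordered
    vals <- raw
    vals[is_missing_cell(raw)] <- NA_character_
  }
  new_omics_table(name, data_type, repr, genes, samples, vals)
}

new_omics_table <- function(name, data_type, repr, genes, samples, values) {
  structure(list(
    name = name, data_type = data_type, internal_repr = repr,
    genes = genes, samples = samples, values = values
  ), class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("omics_table '%s' (%s, %s): %d genes x %d samples\n",
              x$name, x$data_type, x$internal_repr,
              length(x$genes), length(x$samples)))
  invisible(x)
}

#' Parse a sample annotation file
#'
#' Tab-delimited; first column sample id, remaining columns categorical
#' factors. Every sample has a value (possibly `"NA"`) for every factor.
#'
#' @param x path or text.
#' @return a `sample_annotation`: `list(samples, factors)` where `factors`
#'   is a data.frame of character columns, one row per sample.
#' @export
parse_sample_annotation <- function(x) {
  txt <- read_text_arg(x, "sample annotation")
  lines <- split_tsv_lines(txt)
  if (length(lines) < 2L) stopf("sample annotation needs a header and rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stopf("ragged row in sample annotation: line %d", bad)
  }
  header <- cells[[1L]]
  samples <- vapply(cells[-1L], `[[`, "", 1L)
  if (anyDuplicated(samples)) {
    stopf("duplicate sample id '%s' in annotation",
          samples[duplicated(samples)][1L])
  }
  factors <- as.data.frame(
    do.call(rbind, lapply(cells[-1L], `[`, -1L)),
    stringsAsFactors = FALSE
  )
  names(factors) <- header[-1L]
  rownames(factors) <- samples
  structure(list(samples = samples, factors = factors),
            class = "sample_annotation")
}

#' Build sample groups from an annotation factor
#'
#' One group per distinct non-missing level of the factor, in order of
#' first appearance; samples whose level is missing (`"NA"`) belong to no
#' group, so the groups partition the samples that have a level.
#'
#' @param annotation a `sample_annotation`.
#' @param factor factor (column) name.
#' @return list of `sample_group` objects:
#'   `list(group_id, factor, level, members)`.
#' @export
build_groups <- function(annotation, factor) {
  if (!factor %in% names(annotation$factors)) {
    stopf("unknown factor '%s'; available factors: %s", factor,
          paste(names(annotation$factors), collapse = ", "))
  }
  col <- annotation$factors[[factor]]
  keep <- !is_missing_cell(col)
  levels <- unique(col[keep])
  lapply(levels, function(lv) {
    structure(list(
      group_id = paste0(factor, ":", lv), factor = factor, level = lv,
      members = annotation$samples[keep & col == lv]
    ), class = "sample_group")
  })
}

#' Summarize a sample group to one value per gene
#'
#' The summarization rule follows the table's internal representation:
#' continuous values are averaged by default (median, min or max on
#' request); mutation (discrete unordered) tables use the "at least one
#' member of the group is mutated" rule; discrete ordered tables take the
#' modal value, breaking ties toward the value of largest magnitude; set
#' tables take the union. A gene whose members are all missing stays
#' missing.
#'
#' @param table an `omics_table`.
#' @param group a `sample_group`, or a character vector of sample ids.
#' @param method continuous-only override: `"mean"` (default), `"median"`,
#'   `"min"`, `"max"`.
#' @return named vector, one entry per gene of the table (numeric, logical
#'   for discrete_unordered/set).
#' @export
summarize_group <- function(table, group, method = NULL) {
  members <- if (inherits(group, "sample_group")) group$members else group
  members <- intersect(members, table$samples)
  if (length(members) == 0L) {
    stopf("no member of the group is a sample of table '%s'", table$name)
  }
  v <- table$values[, members, drop = FALSE]
  out <- switch(table$internal_repr,
    continuous = {
      method <- match.arg(method %||% "mean", c("mean", "median", "min", "max"))
      fn <- switch(method, mean = rowMeans,
                   median = function(m, na.rm) apply(m, 1L, stats::median, na.rm = na.rm),
                   min = function(m, na.rm) suppressWarnings(apply(m, 1L, min, na.rm = na.rm)),
                   max = function(m, na.rm) suppressWarnings(apply(m, 1L, max, na.rm = na.rm)))
      r <- fn(v, na.rm = TRUE)
      r[!is.finite(r)] <- NA_real_
      r
    },
    discrete_ordered = apply(v, 1L, mode_largest_magnitude),
    discrete_unordered = apply(v, 1L, function(row) {
      m <- is_mutated(row)
      if (all(is.na(m))) NA else any(m, na.rm = TRUE)
    }),
    set = apply(v, 1L, function(row) {
      if (all(is.na(row))) NA else any(row, na.rm = TRUE)
    })
  )
  names(out) <- table$genes
  out
}

# Modal value; ties broken toward the value of largest absolute value
# (so a -2/+2 tie in copy-number calls resolves away from neutral).
mode_largest_magnitude <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  cand[which.max(abs(cand))]
}
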