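#' @title Module enrichment
#' @description
#' The functional-analysis statistic: a standard hypergeometric test of an
#' uploaded gene list against every module of the map. The universe is
#' the set of distinct symbols present on the map (the test asks "which
#' module of this map is enriched", not a genome-wide question), uploaded
#' symbols absent from the map are dropped from the list size, and each
#' symbol counts once per module regardless of how many entity aliases
#' carry it.
#' @name enrichment
NULL

#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` marked items when `n` items are
#' drawn without replacement from a universe of `N` containing `K` marked
#' items:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}}
#' Terms are accumulated in log space for numerical stability at large
#' counts.
#'
#' @param N universe size.
#' @param K marked items in the universe (module size).
#' @param n draws (gene-list size inside the universe).
#' @param k observed overlap.
#' @return the tail probability in `(0, 1]`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  args <- c(N = N, K = K, n = n, k = k)
  if (any(args != round(args)) || any(args < 0)) {
    stopf("hypergeom_tail: N, K, n, k must be non-negative integers")
  }
  if (K > N || n > N) stopf("hypergeom_tail: need K <= N and n <= N")
  if (k > min(K, n)) stopf("hypergeom_tail: need k <= min(K, n)")
  if (k == 0) return(1)
  i <- k:min(K, n)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(logsumexp(logp)))
}

#' Hypergeometric enrichment of a gene list against all map modules
#'
#' For each module: `N` = distinct symbols on the map, `K` = distinct
#' symbols in the module, `n` = distinct uploaded symbols present on the
#' map, `k` = the list/module overlap, with the upper-tail hypergeometric
#' `p_value` and a Benjamini-Hochberg `q_value` across modules (raw P is
#' kept alongside). Rows are sorted by ascending `p_value`.
#'
#' @param map a `network_map` with at least one module.
#' @param gene_list character vector of gene symbols (canonicalized).
#' @return data.frame with columns `module_id, name, N, K, n, k, p_value,
#'   q_value`.
#' @export
module_enrichment <- function(map, gene_list) {
  if (length(map$modules) == 0L) stopf("map '%s' has no modules", map$name)
  universe <- map_symbols(map)
  N <- length(universe)
  glist <- intersect(unique(canon_symbol(gene_list)), universe)
  n <- length(glist)
  if (n == 0L && length(gene_list) > 0L) {
    warning("none of the uploaded symbols are present on the map",
            call. = FALSE)
  }
  ents <- stats::setNames(map$entities, vapply(map$entities, `[[`, "", "id"))
  rows <- lapply(map$modules, function(mod) {
    msym <- unique(unlist(lapply(ents[mod$members], `[[`, "hugo")))
    K <- length(msym)
    k <- length(intersect(glist, msym))
    data.frame(module_id = mod$id, name = mod$name, N = N, K = K, n = n,
               k = k, p_value = hypergeom_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$module_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as tab-delimited text
#'
#' @param enrichment a [module_enrichment()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
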