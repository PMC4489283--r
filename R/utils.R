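# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonicalize gene symbols
#'
#' HUGO symbols are conventionally uppercase; user files vary in case and
#' may carry stray whitespace. All symbol matching in the package goes
#' through this canonical form: uppercase, whitespace-stripped.
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @export
canon_symbol <- function(x) {
  if (length(x) == 0L) return(character())
  toupper(trimws(as.character(x)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All fixture generators route their randomness through this so they are
# pure functions of (spec, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Accept either a path to a text file or literal text (possibly multi-line).
# Returns the content as a single string.
read_text_arg <- function(x, what = "input") {
  if (!is.character(x) || length(x) != 1L) {
    stop(sprintf("%s must be a single string (path or literal text)", what))
  }
  if (!grepl("[\n\t{]", x) && file.exists(x)) {
    return(paste(readLines(x, warn = FALSE), collapse = "\n"))
  }
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
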