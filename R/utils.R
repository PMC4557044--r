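#' @useDynLib radphy, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Derive a stream seed from a master seed
#'
#' Each stochastic stage of the pipeline draws from its own pseudo-random
#' stream, keyed by a label, so that adding or reordering stages never
#' perturbs the draws of earlier ones.
#'
#' @param seed master integer seed.
#' @param label character stream label.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(label)) {
    h <- (h * 69069 + k) %% 2147483647
  }
  as.integer(h) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- alignment container -----------------------------------------------

#' Build an alignment object from gapped strings
#'
#' Alignments are stored as character matrices (one residue per cell) with
#' sequence ids as row names; columns are alignment positions, reported
#' 1-based everywhere.
#'
#' @param strings named character vector of equal-length gapped sequences.
#' @param kind `"protein"` or `"nucleotide"`.
#' @return A matrix of mode character with class `"radphy_alignment"`.
#' @export
as_alignment <- function(strings, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (is.null(names(strings)) || anyNA(names(strings)) || any(names(strings) == ""))
    stop("alignment rows must be named")
  if (anyDuplicated(names(strings)))
    stop("duplicate sequence ids: ", names(strings)[duplicated(names(strings))][1])
  lens <- nchar(strings)
  if (length(unique(lens)) > 1L)
    stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(strings, "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), 0, 0)
  rownames(m) <- names(strings)
  structure(m, class = c("radphy_alignment", class(m)), kind = kind)
}

#' Collapse an alignment back to gapped strings
#' @param aln alignment matrix.
#' @return Named character vector.
#' @export
alignment_strings <- function(aln) {
  if (nrow(aln) == 0L) return(setNames(character(0), character(0)))
  setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

aln_kind <- function(aln) attr(aln, "kind") %||% "protein"

# Column occupancy: fraction of non-gap rows per column.
column_occupancy <- function(aln) {
  if (ncol(aln) == 0L) return(numeric(0))
  colMeans(unclass(aln) != "-")
}

new_alignment_like <- function(m, template) {
  structure(m, class = c("radphy_alignment", class(unclass(m))),
            kind = attr(template, "kind"))
}

#' @export
print.radphy_alignment <- function(x, ...) {
  cat(sprintf("<%s alignment: %d sequences x %d columns>\n",
              aln_kind(x), nrow(x), ncol(x)))
  invisible(x)
}
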