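# Homolog recovery by Smith-Waterman local alignment with affine gaps,
# filtered by Karlin-Altschul E-value and percent-identity gates.

#' Search parameters for homolog recovery
#'
#' Defaults follow BLAST conventions for BLOSUM62 with gap open 11 /
#' extend 1 (gapped Karlin-Altschul parameters lambda = 0.267, K = 0.041).
#' The E-value cutoff defaults to 10 and the identity gate to 0.40 (an
#' alternate 0.20 gate is appropriate for distant, single-genome searches).
#'
#' @param gap_open,gap_extend affine gap penalties (non-negative).
#' @param lambda,K Karlin-Altschul parameters for the scoring system.
#' @param evalue_max E-value cutoff (> 0).
#' @param min_identity identity gate over aligned columns, in (0, 1].
#' @return A list of class `"radphy_search_params"`.
#' @export
search_params <- function(gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041,
                          evalue_max = 10, min_identity = 0.40) {
  stopifnot(evalue_max > 0, min_identity > 0, min_identity <= 1,
            gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, evalue_max = evalue_max,
                 min_identity = min_identity),
            class = "radphy_search_params")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of distinct
#' local alignments with at least the given score between a query of length
#' `m` and a database of total length `n`.
#'
#' @param raw_score integer alignment score.
#' @param m query length; `n` database length (both > 0).
#' @param n database length.
#' @param lambda,K Karlin-Altschul parameters.
#' @return The E-value.
#' @export
karlin_altschul_evalue <- function(raw_score, m, n, lambda = 0.267, K = 0.041) {
  if (m <= 0 || n <= 0) stop("sequence lengths must be positive")
  stopifnot(lambda > 0, K > 0)
  K * m * n * exp(-lambda * raw_score)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps under BLOSUM62. Identity is the fraction
#' of identical residue pairs over aligned (non-gap) columns.
#'
#' @param query,target single named sequences (character) or elements of a
#'   `radphy_seqs` set.
#' @param params [search_params()].
#' @param db_length database length used for the E-value; defaults to the
#'   target length.
#' @return One-row data.frame with columns `query_id`, `target_id`,
#'   `raw_score`, `bitscore`, `evalue`, `aligned_length`, `identity`,
#'   `query_start`, `query_end`, `target_start`, `target_end`.
#' @export
local_align <- function(query, target, params = search_params(),
                        db_length = NULL) {
  qid <- names(query) %||% "query"; tid <- names(target) %||% "target"
  q <- unname(unclass(query)[[1]]); t_ <- unname(unclass(target)[[1]])
  if (nchar(q) == 0L || nchar(t_) == 0L) stop("empty sequence")
  mat <- blosum62_matrix()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t_), type = "local",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, scoreOnly = FALSE)
  sc <- Biostrings::score(pa)
  nm <- Biostrings::nmatch(pa); nmm <- Biostrings::nmismatch(pa)
  aligned_cols <- nm + nmm
  identity <- if (aligned_cols > 0) nm / aligned_cols else 0
  n <- db_length %||% nchar(t_)
  if (sc <= 0) {
    return(data.frame(query_id = qid, target_id = tid, raw_score = 0,
                      bitscore = -log(params$K) / log(2), evalue = karlin_altschul_evalue(0, nchar(q), n, params$lambda, params$K),
                      aligned_length = 0L, identity = 0,
                      query_start = NA_integer_, query_end = NA_integer_,
                      target_start = NA_integer_, target_end = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  data.frame(
    query_id = qid, target_id = tid, raw_score = sc,
    bitscore = (params$lambda * sc - log(params$K)) / log(2),
    evalue = karlin_altschul_evalue(sc, nchar(q), n, params$lambda, params$K),
    aligned_length = nchar(as.character(Biostrings::pattern(pa))),
    identity = identity,
    query_start = Biostrings::start(Biostrings::pattern(pa)),
    query_end = Biostrings::end(Biostrings::pattern(pa)),
    target_start = Biostrings::start(Biostrings::subject(pa)),
    target_end = Biostrings::end(Biostrings::subject(pa)),
    stringsAsFactors = FALSE)
}

#' Find homologs of a query in a sequence database
#'
#' Aligns the query against every database sequence and keeps hits passing
#' both gates (`evalue <= evalue_max` and `identity >= min_identity`),
#' sorted by ascending E-value, then descending score, then target id.
#' E-values use the summed database length.
#'
#' @param query single named protein sequence.
#' @param database `radphy_seqs` (protein) database.
#' @param params [search_params()].
#' @return data.frame of hits (possibly zero rows) with [local_align()]'s
#'   columns.
#' @export
find_homologs <- function(query, database, params = search_params()) {
  if (length(database) == 0L) stop("empty database")
  n_db <- sum(nchar(database))
  hits <- do.call(rbind, lapply(seq_along(database), function(i) {
    local_align(query, database[i], params, db_length = n_db)
  }))
  keep <- hits$evalue <= params$evalue_max & hits$identity >= params$min_identity &
    hits$raw_score > 0
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$raw_score, hits$target_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
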