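# Clade-diagnostic invariant residues, reference-numbering maps, and
# genomic gene-cluster detection.

#' Map alignment columns to reference-sequence numbering
#'
#' Builds the bijection between non-gap columns of the reference row and
#' reference positions `1..L`; reference gap columns map to no position.
#'
#' @param aln alignment containing the reference row.
#' @param reference_id reference row id.
#' @return List with `column_to_position` (length `ncol(aln)`, `NA` at
#'   reference gaps) and `position_to_column` (length `L`).
#' @export
map_alignment_to_reference <- function(aln, reference_id) {
  if (!(reference_id %in% rownames(aln)))
    stop("reference sequence '", reference_id, "' not in alignment")
  ref <- unclass(aln)[reference_id, ]
  nongap <- ref != "-"
  col2pos <- rep(NA_integer_, length(ref))
  col2pos[nongap] <- seq_len(sum(nongap))
  list(column_to_position = col2pos,
       position_to_column = which(nongap))
}

#' Detect clade-diagnostic invariant residues
#'
#' A column is strictly diagnostic when clade A carries exactly one residue
#' and clade B exactly one different residue. In tolerant mode clade A must
#' be invariant, its residue must be absent from clade B, and clade B's
#' majority residue must reach frequency `>= 1 - tau` ("almost invariant").
#' Rows with a gap at a column are excluded from the invariance check, but
#' a clade with more than 50% gaps at a column is ineligible there.
#'
#' @param aln protein alignment.
#' @param cladeA_rows,cladeB_rows disjoint row-id sets (each >= 2).
#' @param reference_id row id providing position numbering.
#' @param mode `"strict"` or `"tolerant"`.
#' @param tau tolerance for clade B in tolerant mode (default 0.1).
#' @return data.frame with columns `column`, `position`, `cladeA_residue`,
#'   `cladeB_majority`, `cladeB_majority_freq`, `strict`.
#' @export
diagnostic_sites <- function(aln, cladeA_rows, cladeB_rows, reference_id,
                             mode = c("tolerant", "strict"), tau = 0.1) {
  mode <- match.arg(mode)
  if (length(intersect(cladeA_rows, cladeB_rows)))
    stop("clade partitions overlap")
  stopifnot(length(cladeA_rows) >= 2L, length(cladeB_rows) >= 2L)
  missing <- setdiff(c(cladeA_rows, cladeB_rows), rownames(aln))
  if (length(missing)) stop("row not in alignment: ", missing[1])
  m <- unclass(aln)
  map <- map_alignment_to_reference(aln, reference_id)
  A <- m[cladeA_rows, , drop = FALSE]
  B <- m[cladeB_rows, , drop = FALSE]
  res <- lapply(seq_len(ncol(m)), function(j) {
    a <- A[, j]; b <- B[, j]
    if (mean(a == "-") > 0.5 || mean(b == "-") > 0.5) return(NULL)
    a <- a[a != "-"]; b <- b[b != "-"]
    if (!length(a) || !length(b)) return(NULL)
    ua <- unique(a)
    if (length(ua) != 1L) return(NULL)         # A must be invariant
    tb <- table(b)
    maj <- names(tb)[which.max(tb)]
    majf <- max(tb) / length(b)
    strict <- length(tb) == 1L && maj != ua
    tolerant <- !(ua %in% names(tb)) && majf >= 1 - tau
    hit <- if (mode == "strict") strict else (strict || tolerant)
    if (!hit) return(NULL)
    data.frame(column = j, position = map$column_to_position[j],
               cladeA_residue = ua, cladeB_majority = maj,
               cladeB_majority_freq = majf, strict = strict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(column = integer(0), position = integer(0),
                      cladeA_residue = character(0), cladeB_majority = character(0),
                      cladeB_majority_freq = numeric(0), strict = logical(0))
  rownames(out) <- NULL
  out
}

#' Test whether focal genes form a physical cluster
#'
#' For a focal pair on one chromosome, reports the gap between their
#' nearest ends (`max(0, later.start - earlier.end - 1)` bp), the number of
#' annotated genes strictly between them, and whether the gap is within
#' `max_distance` (inclusive).
#'
#' @param annotations data.frame as from [read_gff3()].
#' @param focal_ids character vector of two gene ids.
#' @param max_distance clustering threshold in bp (default 50000).
#' @return List with `gene_a`, `gene_b`, `chromosome` (or `NA` if the pair
#'   is unlinked), `distance`, `intervening_genes`, `within_threshold`,
#'   `linked`.
#' @export
gene_clusters <- function(annotations, focal_ids, max_distance = 50000) {
  stopifnot(length(focal_ids) == 2L)
  miss <- setdiff(focal_ids, annotations$gene_id)
  if (length(miss)) stop("focal gene not annotated: ", miss[1])
  a <- annotations[annotations$gene_id == focal_ids[1], ]
  b <- annotations[annotations$gene_id == focal_ids[2], ]
  if (a$chromosome != b$chromosome) {
    return(list(gene_a = focal_ids[1], gene_b = focal_ids[2],
                chromosome = NA_character_, distance = NA_real_,
                intervening_genes = NA_integer_, within_threshold = FALSE,
                linked = FALSE))
  }
  first <- if (a$start <= b$start) a else b
  second <- if (a$start <= b$start) b else a
  dist <- max(0, second$start - first$end - 1)
  chr <- annotations[annotations$chromosome == a$chromosome &
                       !(annotations$gene_id %in% focal_ids), , drop = FALSE]
  n_between <- sum(chr$start > first$end & chr$end < second$start)
  list(gene_a = focal_ids[1], gene_b = focal_ids[2],
       chromosome = a$chromosome, distance = dist,
       intervening_genes = n_between,
       within_threshold = dist <= max_distance, linked = TRUE)
}
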