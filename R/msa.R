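# Alignment construction and filtering: progressive profile alignment on a
# k-mer guide tree, occupancy-based column trimming, removal of poorly
# aligned sequences, codon back-threading, completeness windows and
# clean-data filtering of ambiguous codon columns.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# k-mer cosine distance between ungapped sequences (k = 3, alignment-free),
# used only to build the deterministic guide tree.
kmer_distance <- function(seqs, k = 3L) {
  n <- length(seqs)
  counts <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(table(character(0)))
    table(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  norms <- vapply(counts, function(ct) sqrt(sum(as.numeric(ct)^2)), 0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- intersect(names(counts[[i]]), names(counts[[j]]))
    dot <- sum(as.numeric(counts[[i]][shared]) * as.numeric(counts[[j]][shared]))
    sim <- if (norms[i] > 0 && norms[j] > 0) dot / (norms[i] * norms[j]) else 0
    D[i, j] <- D[j, i] <- 1 - sim
  }
  D
}

# Residue-frequency profile of an alignment block: 20 x ncol, gap mass
# simply reduces a column's weight.
profile_freqs <- function(rows) {
  aa <- rownames(blosum62_matrix())[1:20]
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  f <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = aa))
    as.numeric(tab) / nrow(m)
  }, numeric(20L))
  matrix(f, nrow = 20L, dimnames = list(aa, NULL))
}

align_profiles <- function(rows1, rows2, gap_open, gap_ext) {
  S <- blosum62_matrix()[1:20, 1:20]
  f1 <- profile_freqs(rows1)
  f2 <- profile_freqs(rows2)
  score <- t(f1) %*% S %*% f2
  moves <- gotoh_global(score, gap_open, gap_ext)
  gap1 <- strrep("-", 1L)
  out1 <- character(length(moves)); out2 <- character(length(moves))
  i <- 0L; j <- 0L
  c1 <- lapply(strsplit(rows1, "", fixed = TRUE), identity)
  c2 <- lapply(strsplit(rows2, "", fixed = TRUE), identity)
  m1 <- do.call(rbind, c1); m2 <- do.call(rbind, c2)
  a1 <- matrix("-", nrow(m1), length(moves))
  a2 <- matrix("-", nrow(m2), length(moves))
  for (k in seq_along(moves)) {
    if (moves[k] != 3L) { i <- i + 1L; a1[, k] <- m1[, i] }
    if (moves[k] != 2L) { j <- j + 1L; a2[, k] <- m2[, j] }
  }
  rows <- c(apply(a1, 1L, paste, collapse = ""), apply(a2, 1L, paste, collapse = ""))
  names(rows) <- c(names(rows1), names(rows2))
  rows
}

#' Progressive multiple sequence alignment
#'
#' Aligns protein sequences progressively along a neighbor-joining guide
#' tree built from k-mer cosine distances, merging blocks by profile-profile
#' alignment under BLOSUM62 with affine gap costs. Deterministic for a fixed
#' input order; every input residue appears exactly once, in order, in its
#' row.
#'
#' @param seqs named character vector of ungapped protein sequences.
#' @param gap_open,gap_ext affine gap costs (defaults 11 and 1).
#' @param k k-mer size for the guide-tree distance.
#' @return A `radphy_alignment`.
#' @export
progressive_align <- function(seqs, gap_open = 11, gap_ext = 1, k = 3L) {
  seqs <- gsub("-", "", seqs, fixed = TRUE)
  if (length(seqs) == 0L) stop("no sequences to align")
  if (length(seqs) == 1L) return(as_alignment(seqs, "protein"))
  if (length(seqs) == 2L) {
    rows <- align_profiles(seqs[1], seqs[2], gap_open, gap_ext)
    return(as_alignment(rows, "protein"))
  }
  D <- kmer_distance(seqs, k = k)
  guide <- ape::nj(stats::as.dist(D))
  guide$edge.length[guide$edge.length < 0] <- 0
  # postorder merge
  n <- length(guide$tip.label)
  blocks <- vector("list", n + guide$Nnode)
  for (i in seq_len(n)) blocks[[i]] <- seqs[guide$tip.label[i]]
  ord <- ape::reorder.phylo(guide, "postorder")
  for (r in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[r, 1L]; child <- ord$edge[r, 2L]
    if (is.null(blocks[[parent]])) {
      blocks[[parent]] <- blocks[[child]]
    } else {
      blocks[[parent]] <- align_profiles(blocks[[parent]], blocks[[child]],
                                         gap_open, gap_ext)
    }
  }
  rows <- blocks[[n + 1L]]
  as_alignment(rows[names(seqs)[names(seqs) %in% names(rows)]], "protein")
}

#' Trim low-occupancy alignment columns
#'
#' Keeps exactly the columns whose fraction of non-gap rows is at least
#' `min_occupancy` (inclusive, matching the behavior of phyutility-style
#' `-clean` thresholds on boundary values).
#'
#' @param aln alignment.
#' @param min_occupancy fraction in (0, 1].
#' @return Trimmed alignment; removed column indices (1-based, original
#'   numbering) in attribute `"removed_columns"`.
#' @export
trim_columns <- function(aln, min_occupancy) {
  stopifnot(min_occupancy > 0, min_occupancy <= 1)
  occ <- column_occupancy(aln)
  keep <- occ >= min_occupancy
  if (!any(keep))
    stop("all columns removed; lower min_occupancy")
  out <- new_alignment_like(unclass(aln)[, keep, drop = FALSE], aln)
  attr(out, "removed_columns") <- which(!keep)
  out
}

#' Remove poorly aligned sequences
#'
#' A sequence is poorly aligned when it has residues in fewer than
#' `min_seq_coverage` of the well-occupied core columns (columns with at
#' least 50% non-gap rows).
#'
#' @param aln alignment with at least 2 rows.
#' @param min_seq_coverage coverage threshold in `[0, 1]`, default 0.5.
#' @return Alignment without the removed rows; their ids in attribute
#'   `"removed_sequences"`.
#' @export
remove_poorly_aligned <- function(aln, min_seq_coverage = 0.5) {
  stopifnot(nrow(aln) >= 2L)
  core <- column_occupancy(aln) >= 0.5
  if (!any(core)) stop("no well-occupied core columns")
  cov <- rowMeans(unclass(aln)[, core, drop = FALSE] != "-")
  drop <- cov < min_seq_coverage
  if (all(drop)) stop("all sequences removed; lower min_seq_coverage")
  out <- new_alignment_like(unclass(aln)[!drop, , drop = FALSE], aln)
  attr(out, "removed_sequences") <- rownames(aln)[drop]
  out
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                     if.fuzzy.codon = "solve"))
}

#' Thread CDS onto a protein alignment
#'
#' Each amino-acid column becomes one codon column; protein gaps become
#' `---`. Every CDS must translate exactly to its ungapped protein row.
#'
#' @param aa_aln protein alignment.
#' @param cds named character vector of CDS (ungapped, length divisible by 3).
#' @return Named character vector of gapped codon rows with class
#'   `"radphy_codon_alignment"`.
#' @export
backtranslate <- function(aa_aln, cds) {
  rows <- alignment_strings(aa_aln)
  missing <- setdiff(names(rows), names(cds))
  if (length(missing)) stop("no CDS for sequence: ", missing[1])
  out <- character(length(rows))
  for (i in seq_along(rows)) {
    id <- names(rows)[i]
    aa <- strsplit(rows[[i]], "")[[1]]
    prot <- paste(aa[aa != "-"], collapse = "")
    cd <- cds[[id]]
    if (nchar(cd) %% 3L != 0L) stop("CDS length of '", id, "' not divisible by 3")
    tr <- translate_cds(cd)
    cd_body <- cd
    if (substring(tr, nchar(tr)) == "*") {   # trailing stop codon tolerated
      tr <- substr(tr, 1L, nchar(tr) - 1L)
      cd_body <- substr(cd, 1L, nchar(cd) - 3L)
    }
    if (grepl("*", tr, fixed = TRUE))
      stop(sprintf("internal stop codon in CDS of '%s'", id))
    if (toupper(tr) != toupper(prot)) {
      t1 <- strsplit(toupper(tr), "")[[1]]; t2 <- strsplit(toupper(prot), "")[[1]]
      len <- min(length(t1), length(t2))
      d <- which(t1[seq_len(len)] != t2[seq_len(len)])[1]
      if (is.na(d)) d <- len + 1L
      stop(sprintf("translation of '%s' disagrees with protein row at position %d", id, d))
    }
    codons <- substring(cd_body, seq(1L, nchar(cd_body), 3L), seq(3L, nchar(cd_body), 3L))
    cells <- rep("---", length(aa))
    cells[aa != "-"] <- codons
    out[i] <- paste(cells, collapse = "")
  }
  structure(setNames(out, names(rows)), class = "radphy_codon_alignment")
}

#' @export
`[.radphy_codon_alignment` <- function(x, i) {
  structure(NextMethod(), class = "radphy_codon_alignment")
}

#' @export
print.radphy_codon_alignment <- function(x, ...) {
  cat(sprintf("<codon alignment: %d sequences x %d codons>\n",
              length(x), nchar(x[[1]]) %/% 3L))
  invisible(x)
}

codon_rows_matrix <- function(caln) {
  n <- nchar(caln[[1]])
  stopifnot(n %% 3L == 0L)
  starts <- seq(1L, n, by = 3L)
  m <- t(vapply(caln, function(s) substring(s, starts, starts + 2L),
                character(length(starts))))
  if (length(starts) == 1L) m <- matrix(m, ncol = 1L)
  rownames(m) <- names(caln)
  m
}

codon_matrix_to_caln <- function(m) {
  structure(setNames(apply(m, 1L, paste, collapse = ""), rownames(m)),
            class = "radphy_codon_alignment")
}

#' Keep only sequences complete over a reference codon window
#'
#' Retains rows with no gaps in the alignment columns spanned by positions
#' `first` .. `last` of the (ungapped) reference row, mirroring
#' completeness filters such as "complete between codons 39 and 436".
#'
#' @param aln alignment (protein; one column per codon).
#' @param first,last window bounds in reference numbering (1-based, inclusive).
#' @param reference_id row id providing the numbering.
#' @return Filtered alignment; removed ids in attribute `"removed_sequences"`.
#' @export
window_complete_filter <- function(aln, first, last, reference_id) {
  map <- map_alignment_to_reference(aln, reference_id)
  if (first < 1L || last > length(map$position_to_column) || first > last)
    stop("window outside reference length")
  cols <- map$position_to_column[first]:map$position_to_column[last]
  ok <- rowSums(unclass(aln)[, cols, drop = FALSE] == "-") == 0L
  if (!any(ok)) stop("no sequence complete over the window")
  out <- new_alignment_like(unclass(aln)[ok, , drop = FALSE], aln)
  attr(out, "removed_sequences") <- rownames(aln)[!ok]
  out
}

#' Remove codon columns with gaps or ambiguous data
#'
#' The clean-data rule: a codon column is dropped if any row has a gap or a
#' non-ACGT character in it.
#'
#' @param caln codon alignment.
#' @return Cleaned codon alignment; removed codon-column indices (1-based)
#'   in attribute `"removed_columns"`.
#' @export
clean_codon_columns <- function(caln) {
  m <- codon_rows_matrix(caln)
  bad <- apply(m, 2L, function(col) any(grepl("[^ACGT]", col)))
  if (all(bad)) stop("all codon columns removed by clean-data filtering")
  out <- codon_matrix_to_caln(m[, !bad, drop = FALSE])
  attr(out, "removed_columns") <- which(bad)
  attr(out, "kept_columns") <- which(!bad)
  out
}
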