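# Readers and writers for the external formats the pipeline touches:
# FASTA (protein / CDS), newick trees, GFF3 gene annotations and the
# trait CSV. Genomic coordinates are kept 1-based inclusive as in GFF3;
# alignment columns are 1-based in every report.

PROTEIN_CHARS <- "ACDEFGHIKLMNPQRSTVWYX*"
NUC_CHARS <- "ACGTN"
TRAIT_STATES <- c("anthocyanin", "betalain", "missing")

new_seqset <- function(residues, ids, kind) {
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  residues <- toupper(residues)
  ok_chars <- if (kind == "cds") NUC_CHARS else PROTEIN_CHARS
  bad <- !grepl(sprintf("^[%s]*$", ok_chars), residues)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- setdiff(strsplit(residues[i], "")[[1]], strsplit(ok_chars, "")[[1]])[1]
    stop(sprintf("illegal character '%s' in sequence '%s'", ch, ids[i]))
  }
  if (kind == "cds" && any(nchar(residues) %% 3L != 0L)) {
    i <- which(nchar(residues) %% 3L != 0L)[1]
    stop(sprintf("CDS length of '%s' (%d) is not divisible by 3", ids[i], nchar(residues[i])))
  }
  structure(setNames(residues, ids), kind = kind, class = "radphy_seqs")
}

#' @export
print.radphy_seqs <- function(x, ...) {
  cat(sprintf("<%d %s sequences>\n", length(x), attr(x, "kind")))
  invisible(x)
}

#' @export
`[.radphy_seqs` <- function(x, i) {
  structure(NextMethod(), kind = attr(x, "kind"), class = "radphy_seqs")
}

#' Read sequences from a FASTA file
#'
#' Record ids are taken as the first whitespace-delimited token of the
#' header. CDS records must have length divisible by 3; characters outside
#' the IUPAC alphabet (plus `X` for protein, `N` for nucleotide) are
#' rejected.
#'
#' @param path FASTA file.
#' @param kind `"protein"` or `"cds"`.
#' @return Named character vector of residues with class `"radphy_seqs"`.
#' @export
read_fasta <- function(path, kind = c("protein", "cds")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  new_seqset(as.character(ss), ids, kind)
}

#' Write sequences to a FASTA file
#'
#' Lines are wrapped at 80 columns; `read_fasta(write_fasta(x))` is the
#' identity on ids and residues.
#'
#' @param seqs named character vector of ungapped sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids) && length(seqs) > 0L) stop("sequences must be named")
  if (anyDuplicated(ids)) stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[[i]]
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = 80L)
      writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read a newick tree
#'
#' Branch lengths and integer support values (on internal nodes) are
#' preserved; tip labels must be unique.
#'
#' @param path newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error: ", conditionMessage(e)),
                 warning = function(w) stop("newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) stop("newick parse error: no tree in file")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

#' Write a tree as newick
#' @param tree phylo object.
#' @param path optional output file; if `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read gene annotations from GFF3
#'
#' Only features of type `gene` are retained. Coordinates stay 1-based
#' inclusive exactly as in the file.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (anyDuplicated(ids)) stop("duplicate gene_id: ", ids[duplicated(ids)][1])
  df <- data.frame(
    gene_id = as.character(ids),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(df$start > df$end)) stop("annotation with start > end")
  if (any(df$start < 1L)) stop("annotation with start < 1")
  df
}

#' Write gene annotations as GFF3
#' @param annotations data.frame as returned by [read_gff3()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tradphy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotations$chromosome, annotations$start, annotations$end,
                     ifelse(annotations$strand %in% c("+", "-"), annotations$strand, "+"),
                     annotations$gene_id), con)
  invisible(path)
}

#' Read the trait table
#'
#' A CSV with columns `otu,state`; states must be one of
#' `anthocyanin`, `betalain`, `missing`.
#'
#' @param path CSV file.
#' @return Named character vector: OTU label -> state.
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("otu", "state") %in% names(df)))
    stop("trait CSV must have columns otu,state")
  bad <- setdiff(unique(df$state), TRAIT_STATES)
  if (length(bad))
    stop(sprintf("unknown trait state '%s'; allowed: %s",
                 bad[1], paste(TRAIT_STATES, collapse = ", ")))
  if (anyDuplicated(df$otu)) stop("duplicate OTU label: ", df$otu[duplicated(df$otu)][1])
  setNames(df$state, df$otu)
}

#' Write a trait table as CSV
#' @param traits named character vector of states.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(traits, path) {
  utils::write.csv(data.frame(otu = names(traits), state = unname(traits)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map gene-tree tip labels to species labels
#'
#' Gene tips follow the `species@gene_id` convention; the species label is
#' the prefix before the first delimiter (labels without a delimiter map to
#' themselves).
#'
#' @param labels character vector of gene tip labels.
#' @param delim delimiter, default `"@"`.
#' @return Character vector of species labels.
#' @export
tip_species <- function(labels, delim = "@") {
  vapply(strsplit(labels, delim, fixed = TRUE), `[[`, "", 1L)
}
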