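# Gene-tree estimation from protein alignments: ML pairwise distances under
# an empirical amino-acid model (WAG), neighbor joining, likelihood-based
# refinement (branch lengths + NNI), and nonparametric bootstrap support.

aln_to_phydat <- function(aln) {
  m <- unclass(aln)
  phangorn::phyDat(m, type = "AA")
}

#' ML distance between two aligned protein rows
#'
#' Maximum-likelihood distance (substitutions/site) under the given
#' empirical model, computed over shared non-gap columns and capped at
#' `t_max`.
#'
#' @param s1,s2 gapped strings of equal length.
#' @param model amino-acid model name (default `"WAG"`).
#' @param t_max saturation cap (default 10).
#' @return Non-negative distance.
#' @export
ml_distance <- function(s1, s2, model = "WAG", t_max = 10) {
  stopifnot(nchar(s1) == nchar(s2))
  a <- strsplit(toupper(s1), "")[[1]]; b <- strsplit(toupper(s2), "")[[1]]
  shared <- a != "-" & b != "-"
  if (!any(shared)) stop("no shared non-gap columns")
  if (all(a[shared] == b[shared])) return(0)
  aln <- as_alignment(c(A = s1, B = s2), "protein")
  d <- phangorn::dist.ml(aln_to_phydat(aln), model = model)
  min(as.numeric(d), t_max)
}

#' Pairwise ML distance matrix for an alignment
#' @param aln protein alignment.
#' @param model amino-acid model (default WAG).
#' @param t_max saturation cap.
#' @return Symmetric matrix with zero diagonal.
#' @export
ml_distance_matrix <- function(aln, model = "WAG", t_max = 10) {
  d <- as.matrix(phangorn::dist.ml(aln_to_phydat(aln), model = model))
  d[!is.finite(d)] <- t_max
  d[d > t_max] <- t_max
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration; negative branch lengths are clamped to zero
#' with the deficit transferred to the adjacent (sibling) branch so that
#' path lengths are approximately preserved.
#'
#' @param D symmetric distance matrix (>= 3 taxa).
#' @return Unrooted phylo tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sib <- which(tr$edge[, 1L] == parent & seq_along(tr$edge.length) != e)
    if (length(sib)) {
      s <- sib[1L]
      tr$edge.length[s] <- max(0, tr$edge.length[s] + deficit)
    }
  }
  tr
}

#' Likelihood-based refinement of a tree
#'
#' Optimizes branch lengths under the empirical amino-acid model, and
#' optionally improves the topology by NNI hill-climbing until a local
#' optimum. The returned likelihood never decreases relative to the input
#' tree scored under the same model.
#'
#' @param tree starting phylo tree whose tips match the alignment rows.
#' @param aln protein alignment.
#' @param model amino-acid model name (default WAG).
#' @param max_nni_rounds 0 disables topology moves (branch lengths only).
#' @return Refined tree; the optimized log-likelihood in attribute `"logLik"`.
#' @export
ml_refine <- function(tree, aln, model = "WAG", max_nni_rounds = 5L) {
  stopifnot(setequal(tree$tip.label, rownames(aln)))
  dat <- aln_to_phydat(aln)
  tr <- tree
  if (!is.null(tr$edge.length)) tr$edge.length[tr$edge.length <= 0] <- 1e-8
  fit <- phangorn::pml(tr, dat, model = model)
  fit <- phangorn::optim.pml(fit, model = model, optEdge = TRUE,
                             optNni = max_nni_rounds > 0L,
                             control = phangorn::pml.control(trace = 0))
  out <- fit$tree
  attr(out, "logLik") <- as.numeric(stats::logLik(fit))
  out
}

#' Bootstrap support values
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `builder`, and writes the percentage of replicates
#' containing each internal bipartition onto the node labels of the base
#' tree.
#'
#' @param aln protein alignment.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed; the run is reproducible given the seed.
#' @param tree optional base tree; by default NJ on ML distances.
#' @param builder function(alignment) -> phylo used for base and replicate
#'   trees; default `nj_tree(ml_distance_matrix(.))`.
#' @param model amino-acid model for the default builder.
#' @return Base tree with integer support (0-100) in `node.label`.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L, tree = NULL,
                              builder = NULL, model = "WAG") {
  stopifnot(n_reps >= 1L)
  if (is.null(builder))
    builder <- function(a) nj_tree(ml_distance_matrix(a, model = model))
  base <- tree %||% builder(aln)
  m <- unclass(aln)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      builder(new_alignment_like(m[, cols, drop = FALSE], aln))
    })
  })
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps)
  out <- base
  out$node.label <- as.character(support)
  if (!ape::is.rooted(out)) out$node.label[1] <- ""
  out
}
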