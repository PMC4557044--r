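# Gene-tree surgery rules: long-branch pruning anchored on a reference
# sequence, long-tip removal, anchored clade extraction, and outgroup
# rooting. All thresholds use a strictly-greater comparison ("longer
# than"), and every operation preserves path lengths between retained tips.

#' Prune long branches, keeping the anchor's component
#'
#' Every edge strictly longer than `max_branch` is cut and only the
#' connected component containing the anchor tip is retained; the rule is
#' applied repeatedly until no offending edge remains. Long internal or
#' pendant branches typically join distant paralogs or artifactual
#' sequences.
#'
#' @param tree phylo tree.
#' @param max_branch threshold in substitutions/site (default 1.5).
#' @param anchor_id tip that must survive.
#' @return Pruned tree; removed tip ids in attribute `"removed_tips"`.
#' @export
prune_long_branches <- function(tree, max_branch = 1.5, anchor_id) {
  if (!(anchor_id %in% tree$tip.label)) stop("anchor '", anchor_id, "' not in tree")
  removed <- character(0)
  repeat {
    off <- which(tree$edge.length > max_branch)
    if (!length(off)) break
    e <- off[1L]
    child <- tree$edge[e, 2L]
    below <- if (child <= length(tree$tip.label)) child
             else unlist(phangorn::Descendants(tree, child, "tips"))
    below_labels <- tree$tip.label[below]
    if (anchor_id %in% below_labels) {
      doomed <- setdiff(tree$tip.label, below_labels)
    } else {
      doomed <- below_labels
    }
    if (!length(doomed) || length(setdiff(tree$tip.label, doomed)) < 2L)
      stop("pruning would leave fewer than 2 tips")
    removed <- c(removed, doomed)
    tree <- ape::drop.tip(tree, doomed)
    if (is.null(tree) || !(anchor_id %in% tree$tip.label))
      stop("internal error: anchor lost during pruning")
  }
  attr(tree, "removed_tips") <- removed
  tree
}

#' Remove tips on long pendant branches
#'
#' Tips whose pendant edge is strictly longer than `max_tip_branch` are
#' dropped; resulting unary nodes are suppressed with branch lengths
#' summed.
#'
#' @param tree phylo tree with >= 3 tips.
#' @param max_tip_branch threshold (default 1.0).
#' @return Pruned tree; removed tip ids in attribute `"removed_tips"`.
#' @export
prune_long_tips <- function(tree, max_tip_branch = 1.0) {
  stopifnot(length(tree$tip.label) >= 3L)
  pend <- tree$edge[, 2L] <= length(tree$tip.label)
  long <- pend & tree$edge.length > max_tip_branch
  doomed <- tree$tip.label[tree$edge[long, 2L]]
  if (length(tree$tip.label) - length(doomed) < 2L)
    stop("tip pruning would leave fewer than 2 tips")
  out <- if (length(doomed)) ape::drop.tip(tree, doomed) else tree
  attr(out, "removed_tips") <- doomed
  out
}

#' Extract the smallest clade around an anchor
#'
#' With `target_tips`, returns the smallest clade containing the anchor and
#' all targets. Otherwise the anchor's clade is expanded by
#' `n_outgroup_lineages` successively more inclusive sister lineages
#' (default 1: the anchor plus its closest sister lineage).
#'
#' @param tree rooted phylo tree.
#' @param anchor_id anchor tip label.
#' @param target_tips optional tip set to enclose.
#' @param n_outgroup_lineages expansion steps when `target_tips` is absent
#'   or resolves to the anchor alone.
#' @return The extracted clade as a phylo tree.
#' @export
extract_anchored_clade <- function(tree, anchor_id, target_tips = NULL,
                                   n_outgroup_lineages = 1L) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!(anchor_id %in% tree$tip.label)) stop("anchor '", anchor_id, "' not in tree")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- function(node) tree$edge[tree$edge[, 2L] == node, 1L]
  target_tips <- union(target_tips, anchor_id)
  bad <- setdiff(target_tips, tree$tip.label)
  if (length(bad)) stop("target tip not in tree: ", bad[1])
  if (length(target_tips) > 1L) {
    node <- ape::getMRCA(tree, target_tips)
  } else {
    node <- which(tree$tip.label == anchor_id)
    for (i in seq_len(n_outgroup_lineages)) {
      if (node == root) break
      node <- parent_of(node)
    }
  }
  if (node == root) return(tree)
  ape::extract.clade(tree, node)
}

#' Root a tree with outgroup taxa
#'
#' Places the root at the midpoint of the edge subtending the smallest
#' clade containing all present outgroup labels. Errors if no outgroup tip
#' is present or the outgroup does not form a separable split.
#'
#' @param tree phylo tree.
#' @param outgroup_labels candidate outgroup tip labels (any subset present
#'   is used).
#' @return Rooted tree.
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  present <- intersect(outgroup_labels, tree$tip.label)
  if (!length(present)) stop("no outgroup tip present in tree")
  ingroup <- setdiff(tree$tip.label, present)
  if (!length(ingroup)) stop("outgroup spans the whole tree; not separable")
  # view the tree from an ingroup tip so any outgroup split shows as a clade
  g <- which(tree$tip.label == ingroup[1L])
  pend <- tree$edge.length[tree$edge[, 2L] == g]
  tr <- phytools::reroot(tree, g, position = pend / 2)
  if (length(present) == 1L) {
    node <- which(tr$tip.label == present)
  } else {
    node <- ape::getMRCA(tr, present)
    clade_tips <- tr$tip.label[unlist(phangorn::Descendants(tr, node, "tips"))]
    if (!setequal(clade_tips, present))
      stop("outgroup is not separable (not monophyletic on this tree)")
  }
  stem <- tr$edge.length[tr$edge[, 2L] == node]
  phytools::reroot(tr, node, position = stem / 2)
}
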