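# Gene-tree / species-tree LCA reconciliation: duplication detection and
# placement, ortholog presence/absence matrices, and loss-asymmetry
# summaries between paralog clades.

# For each node of a rooted tree, the set of ancestors (root last).
ancestor_table <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  lapply(seq_len(ntip + tree$Nnode), function(v) {
    path <- v
    while (v != root) { v <- parent[v]; path <- c(path, v) }
    path
  })
}

#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps every gene-tree node to the most recent common ancestor, in the
#' species tree, of the species its descendant tips belong to. A gene node
#' is a duplication when its species mapping equals that of at least one
#' child. Each duplication is placed on its mapped species node together
#' with the parent edge, the latest interval in which it can have occurred
#' ("just before the divergence of" that node's descendants).
#'
#' @param gene_tree,species_tree rooted phylo trees.
#' @param delim delimiter mapping gene tips `species@gene` to species.
#' @return List of class `"radphy_reconciliation"`: `lca_map` (gene node ->
#'   species node index), `duplication_nodes`, `n_duplications`,
#'   `placements` (data.frame with mapped species node, its tip set size,
#'   and the parent edge encoded by its upper node).
#' @export
lca_reconcile <- function(gene_tree, species_tree, delim = "@") {
  stopifnot(ape::is.rooted(gene_tree), ape::is.rooted(species_tree))
  sp_of_tip <- tip_species(gene_tree$tip.label, delim)
  unknown <- setdiff(sp_of_tip, species_tree$tip.label)
  if (length(unknown))
    stop("gene tip maps to unknown species: ", unknown[1])
  ntip_g <- length(gene_tree$tip.label)
  ntip_s <- length(species_tree$tip.label)
  anc_s <- ancestor_table(species_tree)
  depth_s <- lengths(anc_s)  # larger = deeper in tree (more ancestors)
  lca2 <- function(a, b) {
    if (a == b) return(a)
    pa <- anc_s[[a]]; pb <- anc_s[[b]]
    common <- intersect(pa, pb)
    common[1L]  # ancestor lists are ordered node -> root
  }
  nn <- ntip_g + gene_tree$Nnode
  map <- integer(nn)
  map[seq_len(ntip_g)] <- match(sp_of_tip, species_tree$tip.label)
  ord <- ape::reorder.phylo(gene_tree, "postorder")
  children <- split(ord$edge[, 2L], ord$edge[, 1L])
  for (v in unique(ord$edge[, 1L])) map[v] <- 0L
  for (r in seq_len(nrow(ord$edge))) {
    p <- ord$edge[r, 1L]; c_ <- ord$edge[r, 2L]
    map[p] <- if (map[p] == 0L) map[c_] else lca2(map[p], map[c_])
  }
  internal <- (ntip_g + 1L):nn
  dup <- vapply(internal, function(v) {
    kids <- children[[as.character(v)]]
    any(map[kids] == map[v])
  }, logical(1))
  dup_nodes <- internal[dup]
  sp_parent <- integer(ntip_s + species_tree$Nnode)
  sp_parent[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  placements <- data.frame(
    gene_node = dup_nodes,
    species_node = map[dup_nodes],
    species_edge_parent = sp_parent[map[dup_nodes]],
    stringsAsFactors = FALSE
  )
  structure(list(lca_map = map, duplication_nodes = dup_nodes,
                 n_duplications = length(dup_nodes), placements = placements,
                 gene_tree = gene_tree, species_tree = species_tree,
                 delim = delim),
            class = "radphy_reconciliation")
}

#' @export
print.radphy_reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation: %d gene tips, %d duplications>\n",
              length(x$gene_tree$tip.label), x$n_duplications))
  invisible(x)
}

#' Count duplications inside a gene-tree clade
#'
#' @param recon result of [lca_reconcile()].
#' @param clade_tips gene-tree tip labels defining the clade (their MRCA).
#' @return Number of duplication nodes within (and including) the clade's
#'   MRCA.
#' @export
count_clade_duplications <- function(recon, clade_tips) {
  gt <- recon$gene_tree
  bad <- setdiff(clade_tips, gt$tip.label)
  if (length(bad)) stop("tip not in gene tree: ", bad[1])
  if (length(clade_tips) == 1L) return(0L)
  node <- ape::getMRCA(gt, clade_tips)
  inside <- c(node, unlist(phangorn::Descendants(gt, node, "all")))
  sum(recon$duplication_nodes %in% inside)
}

#' Ortholog presence/absence matrix
#'
#' One row per species, one boolean column per named paralog clade; an
#' entry is `TRUE` iff the species has at least one gene tip in that
#' clade. Trait states are attached per species when supplied.
#'
#' @param gene_tree gene tree.
#' @param named_clades named list of disjoint gene-tip sets (e.g. alpha /
#'   beta paralog clades).
#' @param species_list species to report (rows).
#' @param delim tip -> species delimiter.
#' @param traits optional trait table (named states).
#' @return data.frame with `species`, one logical column per clade, and
#'   `trait` when given.
#' @export
presence_matrix <- function(gene_tree, named_clades, species_list,
                            delim = "@", traits = NULL) {
  all_tips <- unlist(named_clades)
  if (anyDuplicated(all_tips)) stop("named clades overlap")
  out <- data.frame(species = species_list, stringsAsFactors = FALSE)
  for (cl in names(named_clades)) {
    sp <- unique(tip_species(named_clades[[cl]], delim))
    out[[cl]] <- species_list %in% sp
  }
  if (!is.null(traits)) {
    out$trait <- ifelse(species_list %in% names(traits),
                        unname(traits[species_list]), "missing")
  }
  out
}

#' Loss asymmetry between two paralog clades
#'
#' Among species of a given trait state, tabulates presence/absence of each
#' clade (2x2) and attaches a two-sided Fisher exact p-value. The exact
#' test is an add-on summary, not part of the original duplication-mapping
#' procedure.
#'
#' @param matrix presence matrix from [presence_matrix()] (needs `trait`).
#' @param cladeA,cladeB column names to compare.
#' @param trait_state trait state selecting the species.
#' @return List with the 2x2 `table` (rows clades, cols present/absent)
#'   and `p_value`.
#' @export
loss_asymmetry <- function(matrix, cladeA, cladeB, trait_state) {
  stopifnot(all(c(cladeA, cladeB, "trait") %in% names(matrix)))
  sub <- matrix[matrix$trait == trait_state, , drop = FALSE]
  if (!nrow(sub)) stop("no species with trait state '", trait_state, "'")
  tab <- rbind(c(sum(sub[[cladeA]]), sum(!sub[[cladeA]])),
               c(sum(sub[[cladeB]]), sum(!sub[[cladeB]])))
  dimnames(tab) <- list(c(cladeA, cladeB), c("present", "absent"))
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, p_value = p)
}
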