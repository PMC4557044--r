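# Synthetic-data generators with known truth: pure-birth species trees,
# binary trait histories with forced gain/reversal events, gene families
# with planted duplications and losses, codon alignments with planted
# selection regimes and diagnostic residues, and clustered genome
# annotations. Fixing the seed fixes every emitted byte; each sub-simulator
# draws from its own stream derived from the master seed.

#' Simulate a pure-birth species tree
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate.
#' @param seed integer seed.
#' @param prefix tip label prefix.
#' @return Rooted ultrametric phylo tree with tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1, seed = 1L,
                                  prefix = "sp") {
  if (n_species < 2L) stop("n_species must be >= 2")
  tr <- with_seed(seed, ape::rphylo(n_species, birth = birth_rate, death = 0))
  tr$tip.label <- sprintf("%s%02d", prefix, seq_len(n_species))
  tr
}

stem_edge_of_clade <- function(tree, tips) {
  bad <- setdiff(tips, tree$tip.label)
  if (length(bad)) stop("tip not in tree: ", bad[1])
  node <- if (length(tips) == 1L) which(tree$tip.label == tips)
          else ape::getMRCA(tree, tips)
  below <- if (node <= length(tree$tip.label)) tree$tip.label[node]
           else tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
  if (!setequal(below, tips))
    stop("tip set is not a clade of the tree")
  node
}

#' Simulate a binary trait forward along a tree
#'
#' Symmetric two-state CTMC with the given rate, with optional forced
#' events: a single gain of the derived state on the stem of `gain_clade`
#' and reversals on the stems of `reversal_clades` (each must be nested
#' strictly inside the gain clade; the gain therefore precedes every
#' reversal).
#'
#' @param tree rooted phylo tree.
#' @param trait_rate Mk1 rate for un-forced edges.
#' @param root_state state at the root (default `"anthocyanin"`).
#' @param forced_events list with `gain_clade` (tip set) and optional
#'   `reversal_clades` (list of tip sets).
#' @param seed integer seed.
#' @return List: `traits` (tip states), `node_states` (all nodes, in node
#'   number order).
#' @export
simulate_trait <- function(tree, trait_rate = 0, root_state = "anthocyanin",
                           forced_events = NULL, seed = 1L) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  gain_node <- NA_integer_; rev_nodes <- integer(0)
  if (!is.null(forced_events)) {
    gain_node <- stem_edge_of_clade(tree, forced_events$gain_clade)
    if (gain_node == ntip + 1L)
      stop("gain clade spans the whole tree; forced events need a stem edge")
    for (rc in forced_events$reversal_clades %||% list()) {
      if (!all(rc %in% forced_events$gain_clade) ||
          setequal(rc, forced_events$gain_clade))
        stop("conflicting forced events: reversal clade must be nested inside the gain clade")
      rev_nodes <- c(rev_nodes, stem_edge_of_clade(tree, rc))
    }
    if (gain_node %in% rev_nodes)
      stop("conflicting forced events on one edge")
  }
  states <- integer(nn)  # 1 anthocyanin, 2 betalain
  states[ntip + 1L] <- match(root_state, MK1_STATES)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  ordr <- rev(seq_len(nrow(edges)))  # preorder
  with_seed(seed, {
    for (r in ordr) {
      p <- edges[r, 1L]; ch <- edges[r, 2L]
      if (!is.na(gain_node) && ch == gain_node) {
        states[ch] <- 2L
      } else if (ch %in% rev_nodes) {
        states[ch] <- 1L
      } else {
        P <- mk1_transition(trait_rate, elen[r])
        states[ch] <- sample.int(2L, 1L, prob = P[states[p], ])
      }
    }
  })
  node_states <- setNames(MK1_STATES[states],
                          c(tree$tip.label, as.character((ntip + 1L):nn)))
  list(traits = node_states[seq_len(ntip)],
       node_states = node_states)
}

#' Simulate a gene family on a species tree
#'
#' Builds a gene tree by planting duplications on species-tree edges and
#' losses of named copies in named species. Each duplication entry is a
#' list with `clade` (species tips whose stem edge duplicates), `name` (the
#' new copy), optional `keep` (species retaining the new copy, default all
#' of `clade`), optional `parent_copy` (which existing copy duplicates,
#' default the base copy) and `position` (fraction up the stem edge,
#' default 0.5). Loss entries are lists with `copy` and `species`.
#'
#' @param species_tree rooted species tree.
#' @param dup_spec list of duplication entries (possibly empty).
#' @param loss_spec list of loss entries (possibly empty).
#' @param base_name label of the ancestral copy (default `"beta"`).
#' @param rate_scale multiplier converting species-tree time to
#'   substitutions/site on the gene tree.
#' @param delim species/copy delimiter in tip labels.
#' @return List: `gene_tree` (tips `species@copy`), `truth` with
#'   `n_duplications`, per-duplication species placement nodes, and the
#'   presence matrix of copies per species.
#' @export
simulate_gene_family <- function(species_tree, dup_spec = list(),
                                 loss_spec = list(), base_name = "beta",
                                 rate_scale = 1, delim = "@") {
  gt <- species_tree
  gt$tip.label <- paste0(species_tree$tip.label, delim, base_name)
  gt$node.label <- NULL
  copies <- base_name
  placements <- data.frame(name = character(0), species_node = integer(0),
                           stringsAsFactors = FALSE)
  for (d in dup_spec) {
    keep <- d$keep %||% d$clade
    if (!all(keep %in% d$clade)) stop("keep must be a subset of clade")
    if (!length(keep)) stop("duplication with no surviving species")
    parent_copy <- d$parent_copy %||% base_name
    if (!(parent_copy %in% copies)) stop("unknown parent copy: ", parent_copy)
    pos <- d$position %||% 0.5
    sp_node <- stem_edge_of_clade(species_tree, d$clade)
    # attachment clade in the current gene tree: the parent copy's tips
    attach_tips <- paste0(d$clade, delim, parent_copy)
    attach_tips <- intersect(attach_tips, gt$tip.label)
    if (!length(attach_tips)) stop("parent copy absent from duplication clade")
    where <- if (length(attach_tips) == 1L) which(gt$tip.label == attach_tips)
             else ape::getMRCA(gt, attach_tips)
    stem_len <- gt$edge.length[gt$edge[, 2L] == where]
    if (!length(stem_len)) stop("cannot duplicate on the root edge")
    depths <- ape::node.depth.edgelength(species_tree)
    depth_dup <- depths[sp_node] - pos * stem_len
    if (length(keep) == 1L) {
      tip_depth <- depths[which(species_tree$tip.label == keep)]
      sub <- ape::read.tree(text = sprintf("(%s:%.10f);", keep,
                                           max(tip_depth - depths[sp_node], 1e-8)))
      sub$root.edge <- pos * stem_len
    } else {
      sub <- ape::keep.tip(species_tree, keep)
      # stem length so that the new copy's root sits at the duplication point
      sub$root.edge <- max(depths[ape::getMRCA(species_tree, keep)] - depth_dup, 1e-8)
    }
    sub$node.label <- NULL
    sub$tip.label <- paste0(sub$tip.label, delim, d$name)
    gt <- ape::bind.tree(gt, sub, where = where, position = pos * stem_len)
    copies <- c(copies, d$name)
    placements <- rbind(placements,
                        data.frame(name = d$name, species_node = sp_node,
                                   stringsAsFactors = FALSE))
  }
  for (l in loss_spec) {
    doomed <- intersect(paste0(l$species, delim, l$copy), gt$tip.label)
    if (length(doomed) >= length(gt$tip.label))
      stop("loss specification empties the gene family")
    if (length(doomed)) gt <- ape::drop.tip(gt, doomed)
  }
  if (is.null(gt) || length(gt$tip.label) < 2L)
    stop("loss specification empties the gene family")
  gt$edge.length <- gt$edge.length * rate_scale
  sp <- tip_species(gt$tip.label, delim)
  cp <- sub(paste0("^[^", delim, "]*", delim), "", gt$tip.label)
  presence <- vapply(copies, function(cc)
    species_tree$tip.label %in% sp[cp == cc], logical(length(species_tree$tip.label)))
  rownames(presence) <- species_tree$tip.label
  list(gene_tree = gt,
       truth = list(n_duplications = length(dup_spec),
                    placements = placements,
                    copies = copies,
                    presence = presence))
}

#' Simulate a codon alignment with planted selection and diagnostics
#'
#' Sites are assigned to the site classes of the chosen model; class-2
#' sites of model A evolve with `omega2` on foreground edges only. Codons
#' evolve over the 61 sense codons, so stop codons are never emitted.
#' Diagnostic residues are imposed post hoc: the column is overwritten to
#' be invariant within each partition.
#'
#' @param tree gene tree with branch lengths in substitutions/codon.
#' @param params list: `model` (`"M0"`, `"M1a"`, `"M2a"`, `"A"`), `kappa`,
#'   `omega0`, `omega2`, `p0`, `p1`, `n_codons`.
#' @param foreground_clade tip set of the foreground clade (model A).
#' @param diagnostic_spec list of lists with `site`, `cladeA_residue`,
#'   `cladeB_residue`; clade A is the foreground clade.
#' @param seed integer seed.
#' @param codon_freqs `"equal"` or a 61-vector.
#' @return List: `caln` (codon alignment), `protein` (protein alignment),
#'   `site_classes` (integer per site), `selected_sites` (sites truly
#'   evolving with `omega2 > 1` on the foreground),
#'   `diagnostic_sites` (planted positions).
#' @export
simulate_codon_alignment <- function(tree, params, foreground_clade = NULL,
                                     diagnostic_spec = NULL, seed = 1L,
                                     codon_freqs = "equal") {
  ct <- codon_tables()
  pi_ <- if (is.numeric(codon_freqs)) codon_freqs else rep(1 / ct$n, ct$n)
  model <- params$model %||% "A"
  classes <- model_site_classes(model, params)
  S <- params$n_codons
  stopifnot(S >= 1L)
  fg <- if (!is.null(foreground_clade))
    clade_edges(tree, foreground_clade, include_stem = TRUE) else integer(0)
  if (model %in% c("A") && !length(fg))
    stop("model A simulation requires a foreground clade")
  parts <- codon_rate_parts(params$kappa, pi_)
  scale_rate <- sum(vapply(classes, function(cl)
    cl$prop * (parts["syn"] + cl$bg * parts["nonsyn"]), 0))
  omegas <- sort(unique(unlist(lapply(classes, function(cl) c(cl$bg, cl$fg)))))
  eigs <- lapply(omegas, function(w)
    codon_eigen(codon_rate_matrix(params$kappa, w, pi_, normalize = FALSE) / scale_rate, pi_))
  names(eigs) <- as.character(omegas)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ord <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(ord$edge)))
  out <- with_seed(seed, {
    cls_id <- sample.int(length(classes), S, replace = TRUE,
                         prob = vapply(classes, `[[`, 0, "prop"))
    states <- matrix(NA_integer_, nn, S)
    states[ntip + 1L, ] <- sample.int(ct$n, S, replace = TRUE, prob = pi_)
    for (r in pre) {
      p <- ord$edge[r, 1L]; ch <- ord$edge[r, 2L]; len <- ord$edge.length[r]
      is_fg <- ch %in% fg
      for (ci in unique(cls_id)) {
        w <- if (is_fg) classes[[ci]]$fg else classes[[ci]]$bg
        P <- codon_P(eigs[[as.character(w)]], len)
        sites <- which(cls_id == ci)
        for (s0 in unique(states[p, sites])) {
          grp <- sites[states[p, sites] == s0]
          states[ch, grp] <- sample.int(ct$n, length(grp), replace = TRUE,
                                        prob = P[s0, ])
        }
      }
    }
    list(cls_id = cls_id, states = states)
  })
  tipstates <- out$states[seq_len(ntip), , drop = FALSE]
  rownames(tipstates) <- tree$tip.label
  codmat <- matrix(ct$codons[tipstates], ntip, S, dimnames = list(tree$tip.label, NULL))
  diag_sites <- integer(0)
  if (!is.null(diagnostic_spec)) {
    if (is.null(foreground_clade)) stop("diagnostic_spec requires a foreground clade")
    aa2codon <- function(a) ct$codons[match(a, ct$aa)]
    for (dsp in diagnostic_spec) {
      s <- dsp$site
      if (s < 1L || s > S) stop("diagnostic site outside the alignment")
      inA <- rownames(codmat) %in% foreground_clade
      codmat[inA, s] <- aa2codon(dsp$cladeA_residue)
      codmat[!inA, s] <- aa2codon(dsp$cladeB_residue)
      diag_sites <- c(diag_sites, s)
    }
  }
  selected_truth <- which(vapply(out$cls_id, function(ci)
    classes[[ci]]$fg > 1, TRUE))
  selected_truth <- setdiff(selected_truth, diag_sites)
  caln <- codon_matrix_to_caln(codmat)
  prot <- as_alignment(vapply(alignment_strings_codon(caln), function(s)
    translate_cds(s), ""), "protein")
  list(caln = caln, protein = prot, site_classes = out$cls_id,
       selected_sites = selected_truth, diagnostic_sites = sort(diag_sites))
}

alignment_strings_codon <- function(caln) setNames(as.character(caln), names(caln))

#' Generate a clustered genome annotation
#'
#' Places the two focal genes on one chromosome with the stated gap between
#' nearest ends and exactly `n_intervening` gene features inside the gap;
#' optional decoy genes go elsewhere.
#'
#' @param cluster_spec list: `chromosome`, `focal_ids` (2), `distance` (bp
#'   between nearest ends), `n_intervening`, `gene_length` (default 1500),
#'   `origin` (start of the first focal gene, default 100000).
#' @param decoys optional data.frame of extra annotations to append.
#' @return data.frame of gene annotations (GFF3 semantics, 1-based
#'   inclusive).
#' @export
make_cluster_annotation <- function(cluster_spec, decoys = NULL) {
  cs <- cluster_spec
  len <- cs$gene_length %||% 1500L
  origin <- cs$origin %||% 100000L
  n_int <- cs$n_intervening %||% 0L
  if (n_int * (len + 2L) > cs$distance - 2L && n_int > 0L)
    stop("impossible packing: intervening genes do not fit in the gap")
  a_start <- origin; a_end <- origin + len - 1L
  b_start <- a_end + cs$distance + 1L; b_end <- b_start + len - 1L
  rows <- data.frame(
    gene_id = cs$focal_ids,
    chromosome = cs$chromosome,
    start = c(a_start, b_start), end = c(a_end, b_end),
    strand = "+", stringsAsFactors = FALSE)
  if (n_int > 0L) {
    slot <- (cs$distance - n_int * len) %/% (n_int + 1L)
    starts <- a_end + slot * seq_len(n_int) + len * (seq_len(n_int) - 1L) + 1L
    rows <- rbind(rows, data.frame(
      gene_id = sprintf("%s_intervening%02d", cs$chromosome, seq_len(n_int)),
      chromosome = cs$chromosome,
      start = starts, end = starts + len - 1L,
      strand = "+", stringsAsFactors = FALSE))
  }
  if (!is.null(decoys)) rows <- rbind(rows, decoys)
  rows[order(rows$chromosome, rows$start), , drop = FALSE]
}
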