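# Orchestration of the full analysis: homolog search, the iterative
# alignment / tree-refinement loop with its standard thresholds
# (occupancy 0.01 -> 0.05 -> 0.1, branch pruning > 1.5, tip pruning >
# 1.0), outgroup rooting, duplication mapping, trait ASR, codon-model
# selection tests, diagnostic residues, and gene-cluster detection, with a
# consolidated machine-readable report.

#' Default pipeline configuration
#'
#' Default thresholds follow the workflow's standard settings: search gates
#' (E-value 10, identity 0.40), trim occupancies 0.01/0.05/0.1 across
#' iterations, branch pruning at 1.5 then tip pruning at 1.0, sequence
#' coverage 0.5, BEB threshold 0.95 (0.99 also reported).
#'
#' @param ... overrides.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    delim = "@",
    min_identity = 0.40, evalue_max = 10,
    trim_occupancy = c(0.01, 0.05, 0.1),
    max_branch = 1.5, max_tip_branch = 1.0,
    min_seq_coverage = 0.5,
    n_bootstrap = 100L,
    window = NULL,              # c(first, last) codons on the query reference
    codon_freqs = "f3x4",
    n_starts = 1L,
    max_cluster_distance = 50000,
    stages = c("search", "refine", "reconcile", "asr", "selection",
               "diagnostics", "clusters"),
    seed = 1L
  )
  utils::modifyList(cfg, list(...))
}

#' Iterative homolog-tree refinement
#'
#' The staged loop: align, trim at the first occupancy level, estimate a
#' tree, realign, trim at the second level, estimate a tree, prune branches
#' longer than `max_branch` keeping the anchor's component, extract the
#' anchored clade, realign, remove poorly aligned sequences, trim at the
#' third level, estimate a tree, remove tips on branches longer than
#' `max_tip_branch`, and compute the final ML-refined tree with bootstrap
#' support.
#'
#' @param seqs named ungapped protein sequences (must include the anchor).
#' @param anchor_id anchor sequence id.
#' @param config [pipeline_config()].
#' @param outgroup_species species labels used for mid-loop rooting (needed
#'   by clade extraction); extraction is skipped when none are present.
#' @return List: `alignment` (final protein alignment), `tree` (final tree
#'   with bootstrap support), `log` (per-stage removals).
#' @export
refine_homolog_tree <- function(seqs, anchor_id, config = pipeline_config(),
                                outgroup_species = NULL) {
  if (!(anchor_id %in% names(seqs))) stop("anchor not among input sequences")
  occ <- config$trim_occupancy
  log <- list()
  build <- function(aln) nj_tree(ml_distance_matrix(aln))
  # iteration 1: align + trim 0.01 + tree
  a1 <- progressive_align(unclass(seqs))
  a1 <- trim_columns(a1, occ[1])
  log$trim1 <- attr(a1, "removed_columns")
  t1 <- build(a1)
  # iteration 2: realign (guide order from tree 1), trim 0.05, tree
  ord <- intersect(t1$tip.label, names(seqs))
  a2 <- progressive_align(unclass(seqs)[ord])
  a2 <- trim_columns(a2, occ[2])
  log$trim2 <- attr(a2, "removed_columns")
  t2 <- build(a2)
  # prune long branches, keep the anchor's component
  t2p <- prune_long_branches(t2, config$max_branch, anchor_id)
  log$pruned_branch_tips <- attr(t2p, "removed_tips")
  keep <- t2p$tip.label
  # anchored clade extraction on a rooted view
  og_tips <- keep[tip_species(keep, config$delim) %in% (outgroup_species %||% character(0))]
  if (length(og_tips) && length(setdiff(keep, og_tips)) > 1L) {
    rooted <- root_with_outgroup(t2p, og_tips)
    cl <- extract_anchored_clade(rooted, anchor_id, target_tips = setdiff(keep, og_tips))
    extracted <- union(cl$tip.label, og_tips)  # keep outgroups for rooting later
    log$extraction_removed <- setdiff(keep, extracted)
    keep <- extracted
  } else {
    log$extraction_removed <- character(0)
  }
  # iteration 3: realign survivors, drop poorly aligned rows, trim 0.1
  a3 <- progressive_align(unclass(seqs)[intersect(names(seqs), keep)])
  a3 <- remove_poorly_aligned(a3, config$min_seq_coverage)
  log$poorly_aligned <- attr(a3, "removed_sequences")
  a3 <- trim_columns(a3, occ[3])
  log$trim3 <- attr(a3, "removed_columns")
  t3 <- build(a3)
  # remove long tips, then the final ML tree with support
  t3p <- prune_long_tips(t3, config$max_tip_branch)
  log$pruned_tips <- attr(t3p, "removed_tips")
  afin <- new_alignment_like(unclass(a3)[t3p$tip.label, , drop = FALSE], a3)
  tfin <- ml_refine(nj_tree(ml_distance_matrix(afin)), afin)
  tfin <- bootstrap_support(afin, n_reps = config$n_bootstrap,
                            seed = derive_seed(config$seed, "bootstrap"),
                            tree = tfin)
  if (!(anchor_id %in% tfin$tip.label))
    stop("anchor eliminated during refinement")
  list(alignment = afin, tree = tfin, log = log)
}

# split the gene tree into the anchor's paralog clade (alpha) and its
# sister (beta) at the most basal duplication node on the anchor's path
split_paralog_clades <- function(rooted_gene_tree, recon, anchor_id, delim,
                                 ingroup_species) {
  gt <- rooted_gene_tree
  ntip <- length(gt$tip.label)
  anchor <- which(gt$tip.label == anchor_id)
  parent <- integer(ntip + gt$Nnode)
  parent[gt$edge[, 2L]] <- gt$edge[, 1L]
  path <- anchor
  v <- anchor
  while (v != ntip + 1L) { v <- parent[v]; path <- c(path, v) }
  dups_on_path <- intersect(rev(path), recon$duplication_nodes)  # basal first
  if (!length(dups_on_path)) return(NULL)
  tipset <- function(v) {
    if (v <= ntip) gt$tip.label[v]
    else gt$tip.label[unlist(phangorn::Descendants(gt, v, "tips"))]
  }
  # the alpha/beta split duplicates a whole species clade, so among the
  # candidate duplications on the anchor's path pick the one with the
  # largest set of species present on both sides (ties -> most basal);
  # spurious duplications from tree-estimation noise duplicate few species
  overlap <- vapply(dups_on_path, function(d) {
    kids <- gt$edge[gt$edge[, 1L] == d, 2L]
    length(intersect(tip_species(tipset(kids[1L]), delim),
                     tip_species(tipset(kids[2L]), delim)))
  }, 0L)
  dup <- dups_on_path[which.max(overlap)]
  kids <- gt$edge[gt$edge[, 1L] == dup, 2L]
  side_a <- tipset(kids[1L]); side_b <- tipset(kids[2L])
  alpha <- if (anchor_id %in% side_a) side_a else side_b
  sister <- if (anchor_id %in% side_a) side_b else side_a
  keep_in <- function(tips) tips[tip_species(tips, delim) %in% ingroup_species]
  # the beta partition is every non-alpha family copy in the ingroup: the
  # pre-duplication lineages of species that split off before the
  # duplication carry the ancestral (beta-like) copy
  all_in <- keep_in(gt$tip.label)
  list(alpha = keep_in(alpha), beta = setdiff(all_in, keep_in(alpha)),
       beta_sister = keep_in(sister), dup_node = dup)
}

#' Run the full analysis pipeline
#'
#' Stages (skippable through `config$stages`): homolog search, iterative
#' tree refinement, outgroup rooting and LCA reconciliation with
#' presence/absence and loss-asymmetry summaries, Mk1 trait ASR on the
#' species tree, codon-model selection tests (M1a vs M2a and branch-site
#' model A vs its null, with BEB site posteriors; foreground = all
#' branches within the anchor's paralog clade), clade-diagnostic residues,
#' and gene-cluster detection.
#'
#' @param inputs list: `proteins`, `cds` (`radphy_seqs`), `species_tree`
#'   (phylo), `traits` (named states), `annotations` (data.frame),
#'   `query_id`, `outgroup_species`, optional `focal_ids`. A
#'   `radphy_scenario` can be passed directly.
#' @param config [pipeline_config()].
#' @return List of class `"radphy_report"` with per-stage results.
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  if (inherits(inputs, "radphy_scenario")) {
    inputs <- list(proteins = inputs$proteins, cds = inputs$cds,
                   species_tree = inputs$species_tree, traits = inputs$traits,
                   annotations = inputs$annotations, query_id = inputs$query_id,
                   outgroup_species = inputs$outgroup_species,
                   focal_ids = inputs$truth$focal_ids)
  }
  need <- c("proteins", "species_tree", "traits", "query_id")
  miss <- need[!need %in% names(inputs)]
  if (length(miss)) stop("missing pipeline input: ", miss[1])
  delim <- config$delim
  stages <- config$stages
  report <- list(config = config)

  # search
  db <- inputs$proteins
  if ("search" %in% stages) {
    params <- search_params(evalue_max = config$evalue_max,
                            min_identity = config$min_identity)
    hits <- find_homologs(db[inputs$query_id], db, params)
    report$search <- list(n_hits = nrow(hits), hits = hits)
    seqs <- db[hits$target_id]
  } else {
    seqs <- db
  }

  # refinement loop
  if ("refine" %in% stages) {
    ref <- refine_homolog_tree(seqs, inputs$query_id, config,
                               outgroup_species = inputs$outgroup_species)
    report$refine <- list(
      n_in = length(seqs), n_out = length(ref$tree$tip.label), log = ref$log)
    aln <- ref$alignment
    gene_tree <- ref$tree
  } else {
    aln <- progressive_align(unclass(seqs))
    gene_tree <- nj_tree(ml_distance_matrix(aln))
  }
  og_tips <- gene_tree$tip.label[
    tip_species(gene_tree$tip.label, delim) %in% inputs$outgroup_species]
  rooted <- root_with_outgroup(gene_tree, og_tips)
  report$gene_tree <- rooted

  ingroup_species <- setdiff(inputs$species_tree$tip.label, inputs$outgroup_species)
  clades <- NULL
  if ("reconcile" %in% stages) {
    recon <- lca_reconcile(rooted, inputs$species_tree, delim)
    clades <- split_paralog_clades(rooted, recon, inputs$query_id, delim,
                                   ingroup_species)
    report$reconciliation <- list(
      n_duplications = recon$n_duplications,
      placements = recon$placements)
    if (!is.null(clades)) {
      pm <- presence_matrix(rooted, list(alpha = clades$alpha, beta = clades$beta),
                            ingroup_species, delim, inputs$traits)
      report$presence <- pm
      report$clades <- clades
      report$duplication_species_node <-
        recon$lca_map[clades$dup_node]
      report$n_duplications_alpha <- count_clade_duplications(recon, clades$alpha)
      # beta-side duplications: inside the ingroup family but neither in the
      # alpha clade nor the alpha/beta split itself
      ntip_g <- length(rooted$tip.label)
      in_clade_nodes <- function(tips) {
        if (length(tips) < 2L) return(integer(0))
        n <- ape::getMRCA(rooted, tips)
        c(n, unlist(phangorn::Descendants(rooted, n, "all")))
      }
      fam_nodes <- in_clade_nodes(c(clades$alpha, clades$beta))
      alpha_nodes <- in_clade_nodes(clades$alpha)
      report$n_duplications_beta <- length(setdiff(
        intersect(recon$duplication_nodes, fam_nodes),
        c(alpha_nodes, clades$dup_node)))
      if (any(pm$trait == "anthocyanin"))
        report$loss_asymmetry <- loss_asymmetry(pm, "alpha", "beta", "anthocyanin")
    }
  }

  if ("asr" %in% stages) {
    fit <- fit_mk1(inputs$species_tree, inputs$traits)
    post <- fit$node_posteriors
    ntip_s <- length(inputs$species_tree$tip.label)
    # inferred gain nodes: betalain-majority nodes whose parent is not
    parent <- integer(ntip_s + inputs$species_tree$Nnode)
    parent[inputs$species_tree$edge[, 2L]] <- inputs$species_tree$edge[, 1L]
    bet <- as.integer(rownames(post))[post[, "betalain"] > 0.5]
    gains <- bet[!(parent[bet] %in% bet) & parent[bet] != 0L]
    report$asr <- list(rate = fit$rate, logLik = fit$logLik,
                       neg_logLik = fit$neg_logLik,
                       node_posteriors = post, inferred_gain_nodes = gains)
  }

  if ("selection" %in% stages && !is.null(clades) && !is.null(inputs$cds)) {
    sel_seed <- derive_seed(config$seed, "selection")
    caln <- backtranslate(aln, inputs$cds)
    paln <- aln
    if (!is.null(config$window)) {
      paln <- window_complete_filter(aln, config$window[1], config$window[2],
                                     inputs$query_id)
      caln <- caln[rownames(paln)]
    }
    caln <- clean_codon_columns(caln)
    kept <- attr(caln, "kept_columns")
    refmap <- map_alignment_to_reference(paln, inputs$query_id)
    site_numbers <- refmap$column_to_position[kept]
    ctree <- ape::keep.tip(rooted, names(caln))
    fg <- clade_edges(ctree, intersect(clades$alpha, ctree$tip.label),
                      include_stem = TRUE)
    m1a <- fit_codon_model(ctree, caln, "M1a", codon_freqs = config$codon_freqs,
                           n_starts = config$n_starts, seed = sel_seed)
    m2a <- fit_codon_model(ctree, caln, "M2a", codon_freqs = config$codon_freqs,
                           n_starts = max(2L, config$n_starts), seed = sel_seed,
                           start = nested_start_m2a(m1a$params))
    a_null <- fit_codon_model(ctree, caln, "A_null", foreground_edges = fg,
                              codon_freqs = config$codon_freqs,
                              n_starts = config$n_starts, seed = sel_seed)
    a_alt <- fit_codon_model(ctree, caln, "A", foreground_edges = fg,
                             codon_freqs = config$codon_freqs,
                             n_starts = max(2L, config$n_starts), seed = sel_seed,
                             start = nested_start_modelA(a_null$params))
    beb <- eb_site_posteriors(a_alt, method = "BEB", site_numbers = site_numbers)
    report$selection <- list(
      m1a = m1a$params, m1a_logLik = m1a$logLik,
      m2a = m2a$params, m2a_logLik = m2a$logLik,
      lrt_m1a_m2a = lrt(m1a, m2a),
      modelA = a_alt$params, modelA_logLik = a_alt$logLik,
      modelA_null_logLik = a_null$logLik,
      lrt_modelA = lrt(a_null, a_alt, mixture = TRUE),
      site_posteriors = beb,
      selected_sites_095 = beb$site[beb$selected_095],
      selected_sites_099 = beb$site[beb$selected_099])
  }

  if ("diagnostics" %in% stages && !is.null(clades)) {
    ds <- diagnostic_sites(aln,
                           intersect(clades$alpha, rownames(aln)),
                           intersect(clades$beta, rownames(aln)),
                           inputs$query_id, mode = "tolerant", tau = 0.1)
    report$diagnostics <- ds
  }

  if ("clusters" %in% stages && !is.null(inputs$annotations) &&
      !is.null(inputs$focal_ids)) {
    report$cluster <- gene_clusters(inputs$annotations, inputs$focal_ids,
                                    config$max_cluster_distance)
  }

  class(report) <- "radphy_report"
  report
}

#' @export
print.radphy_report <- function(x, ...) {
  cat("radphy pipeline report\n")
  if (!is.null(x$search)) cat(sprintf("  search: %d hits\n", x$search$n_hits))
  if (!is.null(x$reconciliation))
    cat(sprintf("  duplications: %d (alpha clade: %s)\n",
                x$reconciliation$n_duplications,
                x$n_duplications_alpha %||% "-"))
  if (!is.null(x$asr))
    cat(sprintf("  Mk1 rate: %.5f, -log L: %.5f\n", x$asr$rate, x$asr$neg_logLik))
  if (!is.null(x$selection))
    cat(sprintf("  M1a-vs-M2a LRT p = %.3g; model A LRT p = %.3g; %d sites BEB > 0.95\n",
                x$selection$lrt_m1a_m2a$p_value, x$selection$lrt_modelA$p_value,
                length(x$selection$selected_sites_095)))
  if (!is.null(x$diagnostics))
    cat(sprintf("  diagnostic sites: %s\n",
                paste(x$diagnostics$position, collapse = ", ")))
  if (!is.null(x$cluster) && isTRUE(x$cluster$linked))
    cat(sprintf("  cluster: %d bp apart, %d intervening\n",
                x$cluster$distance, x$cluster$intervening_genes))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report result of [run_pipeline()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  to_json <- list(
    n_hits = report$search$n_hits,
    n_duplications = report$reconciliation$n_duplications,
    n_duplications_alpha = report$n_duplications_alpha,
    n_duplications_beta = report$n_duplications_beta,
    asr_rate = report$asr$rate,
    asr_neg_logLik = report$asr$neg_logLik,
    lrt_m1a_m2a = report$selection$lrt_m1a_m2a,
    lrt_modelA = report$selection$lrt_modelA,
    selected_sites_095 = report$selection$selected_sites_095,
    diagnostic_sites = report$diagnostics$position,
    cluster = report$cluster)
  jsonlite::write_json(to_json, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
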