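# The full synthetic study: a species phylogeny with a small outgroup
# grade, one gain of the derived pigment state and several reversals, a
# gene family that duplicates into alpha/beta paralog clades on the stem of
# the trait-bearing clade (with the alpha copy missing from every reversal
# lineage and an additional radiation inside alpha), codon sequences with
# positive selection restricted to the alpha clade, planted diagnostic
# residues, and a genome annotation in which the two trait loci sit within
# 50 kb with one intervening gene.

scenario_defaults <- function() {
  list(
    n_ingroup = 32L, n_outgroup = 4L, birth_rate = 1,
    gain_fraction = 0.55, n_reversals = 3L, max_reversal_size = 3L,
    rate_scale = 0.4,
    codon = list(model = "A", kappa = 2, omega0 = 0.1, omega2 = 5,
                 p0 = 0.45, p1 = 0.45, n_codons = 210L),
    diagnostics = list(list(site = 50L, cladeA_residue = "P", cladeB_residue = "N"),
                       list(site = 120L, cladeA_residue = "W", cladeB_residue = "A")),
    cluster = list(chromosome = "chr2", distance = 30000L, n_intervening = 1L,
                   gene_length = 1500L),
    n_decoys = 4L, delim = "@"
  )
}

#' Simulate the full study scenario with known truth
#'
#' All defaults are the package's desk-scale study conditions (see the
#' methods vignette); the seed fixes every emitted value.
#'
#' @param seed master integer seed.
#' @param config optional overrides of the defaults (named list).
#' @return List of class `"radphy_scenario"`: `species_tree`, `traits`,
#'   `gene_tree`, `proteins`, `cds`, `annotations`, `query_id`,
#'   `outgroup_species`, plus `truth` (gain clade, reversal clades,
#'   duplication placements, selected/diagnostic sites, presence matrix,
#'   cluster spec).
#' @export
simulate_scenario <- function(seed = 1L, config = list()) {
  cfg <- utils::modifyList(scenario_defaults(), config)
  # unnamed list entries (the diagnostic spec) replace the default wholesale
  # rather than merging element-wise
  if ("diagnostics" %in% names(config)) cfg$diagnostics <- config$diagnostics
  delim <- cfg$delim
  # species tree: outgroup grade joined to the ingroup at depth 1.3
  t_in <- simulate_species_tree(cfg$n_ingroup, cfg$birth_rate,
                                derive_seed(seed, "speciestree_in"), prefix = "sp")
  t_og <- simulate_species_tree(cfg$n_outgroup, cfg$birth_rate,
                                derive_seed(seed, "speciestree_og"), prefix = "og")
  scale_to <- function(tr, h) {
    tr$edge.length <- tr$edge.length * h / max(ape::node.depth.edgelength(tr))
    tr
  }
  t_in <- scale_to(t_in, 1.0)
  t_og <- scale_to(t_og, 0.6)
  nwk <- sprintf("(%s:0.3,%s:0.7);",
                 sub(";$", "", ape::write.tree(t_in)),
                 sub(";$", "", ape::write.tree(t_og)))
  stree <- ape::read.tree(text = nwk)
  ingroup <- t_in$tip.label
  outgroup <- t_og$tip.label

  # trait history: one gain, several nested reversals, no extra noise
  gain_node <- local({  # candidate clades restricted to the ingroup side
    ntip <- length(stree$tip.label)
    in_mrca <- ape::getMRCA(stree, ingroup)
    cand <- intersect(unlist(phangorn::Descendants(stree, in_mrca, "all")),
                      (ntip + 1L):(ntip + stree$Nnode))
    sizes <- vapply(cand, function(v)
      length(unlist(phangorn::Descendants(stree, v, "tips"))), 0L)
    cand[which.min(abs(sizes - cfg$gain_fraction * length(ingroup)))]
  })
  gain_clade <- stree$tip.label[unlist(phangorn::Descendants(stree, gain_node, "tips"))]
  rev_clades <- with_seed(derive_seed(seed, "reversals"), {
    ntip <- length(stree$tip.label)
    cand_nodes <- c(which(stree$tip.label %in% gain_clade),
                    intersect(unlist(phangorn::Descendants(stree, gain_node, "all")),
                              (ntip + 1L):(ntip + stree$Nnode)))
    cand <- lapply(cand_nodes, function(v)
      stree$tip.label[unlist(phangorn::Descendants(stree, v, "tips"))])
    cand <- Filter(function(tp) length(tp) <= cfg$max_reversal_size &&
                     length(tp) < length(gain_clade), cand)
    picked <- list()
    for (i in sample.int(length(cand))) {
      tp <- cand[[i]]
      if (length(intersect(tp, unlist(picked)))) next
      # the alpha copy must survive in at least 2 species
      if (length(setdiff(gain_clade, c(unlist(picked), tp))) < 2L) next
      picked <- c(picked, list(tp))
      if (length(picked) == cfg$n_reversals) break
    }
    picked
  })
  reversal_species <- unlist(rev_clades)
  trait_sim <- simulate_trait(stree, trait_rate = 0,
                              root_state = "anthocyanin",
                              forced_events = list(gain_clade = gain_clade,
                                                   reversal_clades = rev_clades),
                              seed = derive_seed(seed, "trait"))

  # gene family: alpha arises on the gain-clade stem and is absent from
  # every reversal lineage; nested radiation inside alpha; one beta-side
  # duplication in a small anthocyanic clade
  alpha_keep <- setdiff(gain_clade, reversal_species)
  sub_node <- local({   # subclade of the surviving alpha species for the nested dup
    ntip <- length(stree$tip.label)
    cand <- intersect(unlist(phangorn::Descendants(stree, gain_node, "all")),
                      (ntip + 1L):(ntip + stree$Nnode))
    cl <- lapply(cand, function(v)
      stree$tip.label[unlist(phangorn::Descendants(stree, v, "tips"))])
    ok <- which(vapply(cl, function(tp)
      all(tp %in% alpha_keep) && length(tp) >= 3L && length(tp) <= 8L, TRUE))
    if (length(ok)) cand[ok[1L]] else NA_integer_
  })
  dup_spec <- list(list(clade = gain_clade, name = "alpha", keep = alpha_keep,
                        parent_copy = "beta", position = 0.5))
  if (!is.na(sub_node)) {
    sub_clade <- stree$tip.label[unlist(phangorn::Descendants(stree, sub_node, "tips"))]
    dup_spec <- c(dup_spec, list(list(clade = sub_clade, name = "alpha2",
                                      keep = sub_clade, parent_copy = "alpha",
                                      position = 0.5)))
  }
  beta_side <- setdiff(ingroup, gain_clade)
  beta2_clade <- local({
    ntip <- length(stree$tip.label)
    nodes <- c(which(stree$tip.label %in% beta_side),
               (ntip + 1L):(ntip + stree$Nnode))
    cl <- lapply(nodes, function(v)
      stree$tip.label[unlist(phangorn::Descendants(stree, v, "tips"))])
    ok <- which(vapply(cl, function(tp)
      all(tp %in% beta_side) && length(tp) >= 1L && length(tp) <= 3L, TRUE))
    if (length(ok)) cl[[ok[1L]]] else NULL
  })
  if (!is.null(beta2_clade))
    dup_spec <- c(dup_spec, list(list(clade = beta2_clade, name = "beta2",
                                      keep = beta2_clade, parent_copy = "beta",
                                      position = 0.5)))
  fam <- simulate_gene_family(stree, dup_spec, loss_spec = list(),
                              base_name = "beta", rate_scale = cfg$rate_scale,
                              delim = delim)
  gtree <- fam$gene_tree
  alpha_tips <- gtree$tip.label[grepl(paste0(delim, "alpha"), gtree$tip.label)]
  beta_tips <- setdiff(gtree$tip.label[tip_species(gtree$tip.label, delim) %in% ingroup],
                       alpha_tips)

  csim <- simulate_codon_alignment(gtree, cfg$codon,
                                   foreground_clade = alpha_tips,
                                   diagnostic_spec = cfg$diagnostics,
                                   seed = derive_seed(seed, "codons"))
  cds <- new_seqset(gsub("-", "", as.character(csim$caln)), names(csim$caln), "cds")
  prot_str <- vapply(as.character(cds), translate_cds, "")
  proteins <- new_seqset(prot_str, names(cds), "protein")

  # decoy proteins that fail the identity gate
  decoys <- with_seed(derive_seed(seed, "decoys"), {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    setNames(vapply(seq_len(cfg$n_decoys), function(i)
      paste(sample(aa, cfg$codon$n_codons, replace = TRUE), collapse = ""), ""),
      sprintf("decoy%02d", seq_len(cfg$n_decoys)))
  })
  database <- new_seqset(c(unclass(proteins), decoys),
                         c(names(proteins), names(decoys)), "protein")

  genome_sp <- sort(alpha_keep)[1L]
  query_id <- paste0(genome_sp, delim, "alpha")
  focal_ids <- paste0(genome_sp, c("_DODA_alpha", "_CYP_alpha"))
  decoy_ann <- data.frame(
    gene_id = paste0(genome_sp, c("_DODA_beta", "_CYP_beta", "_CYP_gamma")),
    chromosome = c("chr4", "chr1", "chr9"),
    start = c(500000L, 200000L, 350000L),
    end = c(501499L, 201499L, 351499L),
    strand = "+", stringsAsFactors = FALSE)
  annotations <- make_cluster_annotation(
    utils::modifyList(cfg$cluster, list(focal_ids = focal_ids)), decoys = decoy_ann)

  structure(list(
    species_tree = stree, traits = trait_sim$traits,
    gene_tree = gtree, proteins = database, cds = cds,
    annotations = annotations, query_id = query_id,
    outgroup_species = outgroup, ingroup_species = ingroup, delim = delim,
    config = cfg,
    truth = list(
      gain_node = gain_node, gain_clade = gain_clade,
      reversal_clades = rev_clades, reversal_species = reversal_species,
      node_states = trait_sim$node_states,
      duplications = fam$truth, alpha_tips = alpha_tips, beta_tips = beta_tips,
      selected_sites = csim$selected_sites,
      site_classes = csim$site_classes,
      diagnostic_sites = csim$diagnostic_sites,
      diagnostic_spec = cfg$diagnostics,
      focal_ids = focal_ids, cluster = cfg$cluster
    )), class = "radphy_scenario")
}

#' @export
print.radphy_scenario <- function(x, ...) {
  cat(sprintf("<scenario: %d species (+%d outgroup), %d gene tips, %d codons>\n",
              length(x$ingroup_species), length(x$outgroup_species),
              length(x$gene_tree$tip.label), x$config$codon$n_codons))
  invisible(x)
}

#' Write a scenario to disk
#'
#' Emits `species.nwk`, `genetree.nwk`, `proteins.fasta`, `cds.fasta`,
#' `traits.csv`, `genes.gff3` and `truth.json` into `dir`.
#'
#' @param scenario result of [simulate_scenario()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(scenario$species_tree, file.path(dir, "species.nwk"))
  write_newick(scenario$gene_tree, file.path(dir, "genetree.nwk"))
  write_fasta(scenario$proteins, file.path(dir, "proteins.fasta"))
  write_fasta(scenario$cds, file.path(dir, "cds.fasta"))
  write_trait_csv(scenario$traits, file.path(dir, "traits.csv"))
  write_gff3(scenario$annotations, file.path(dir, "genes.gff3"))
  tr <- scenario$truth
  jsonlite::write_json(list(
    gain_clade = tr$gain_clade,
    reversal_species = tr$reversal_species,
    n_duplications = tr$duplications$n_duplications,
    selected_sites = tr$selected_sites,
    diagnostic_sites = tr$diagnostic_sites,
    query_id = scenario$query_id,
    focal_ids = tr$focal_ids
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
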