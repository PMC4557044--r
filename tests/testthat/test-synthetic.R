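test_that("species-tree simulation is ultrametric, sized, and seed-stable", {
  tr <- simulate_species_tree(50, 1, seed = 3)
  expect_equal(length(tr$tip.label), 50L)
  expect_equal(tr$Nnode, 49L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_species_tree(50, 1, seed = 3)))
  expect_error(simulate_species_tree(1), ">= 2")
  cherry <- simulate_species_tree(2, 1, seed = 1)
  expect_equal(length(cherry$tip.label), 2L)
})

test_that("trait simulation honours rate zero, forced events and nesting rules", {
  tr <- simulate_species_tree(12, 1, seed = 5)
  quiet <- simulate_trait(tr, trait_rate = 0, seed = 1)
  expect_true(all(quiet$traits == "anthocyanin"))
  gain <- pick_subclade(tr, 3, 6)
  forced <- simulate_trait(tr, 0, forced_events = list(gain_clade = gain), seed = 1)
  expect_true(all(forced$traits[gain] == "betalain"))
  expect_true(all(forced$traits[setdiff(tr$tip.label, gain)] == "anthocyanin"))
  expect_error(
    simulate_trait(tr, 0, forced_events = list(gain_clade = gain,
                                               reversal_clades = list(gain)), seed = 1),
    "nested")
  # a reversal outside the gain clade conflicts
  expect_error(
    simulate_trait(tr, 0, forced_events = list(
      gain_clade = gain,
      reversal_clades = list(setdiff(tr$tip.label, gain)[1])), seed = 1),
    "nested")
})

test_that("high trait rates produce both states and converge to 1/2 each", {
  tr <- simulate_species_tree(200, 1, seed = 8)
  sim <- simulate_trait(tr, trait_rate = 1, seed = 4)
  expect_setequal(unique(sim$traits), c("anthocyanin", "betalain"))
  # at very large rate tip states are a fair coin: chi-squared over replicates
  counts <- vapply(1:10, function(i) {
    s <- simulate_trait(tr, trait_rate = 50, seed = 100 + i)$traits
    sum(s == "betalain")
  }, 0)
  p <- stats::chisq.test(c(sum(counts), 10 * 200 - sum(counts)))$p.value
  expect_gt(p, 0.001)
})

test_that("gene-family simulation plants duplications and matches tip truth", {
  st <- simulate_species_tree(8, 1, seed = 2)
  plain <- simulate_gene_family(st)
  relabelled <- plain$gene_tree
  relabelled$tip.label <- tip_species(relabelled$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(relabelled), ape::unroot(st))), 0)
  expect_equal(plain$truth$n_duplications, 0L)
  clade <- pick_subclade(st, 2, 5)
  fam <- simulate_gene_family(st, dup_spec = list(list(clade = clade, name = "alpha")))
  expect_equal(fam$truth$n_duplications, 1L)
  # one tip per surviving (species, copy)
  expect_setequal(fam$gene_tree$tip.label,
                  c(paste0(st$tip.label, "@beta"), paste0(clade, "@alpha")))
  # presence truth equals presence recomputed from tips
  sp <- tip_species(fam$gene_tree$tip.label)
  cp <- sub("^[^@]*@", "", fam$gene_tree$tip.label)
  for (cc in colnames(fam$truth$presence))
    expect_setequal(rownames(fam$truth$presence)[fam$truth$presence[, cc]],
                    unique(sp[cp == cc]))
  # losses remove the alpha copy from chosen species
  lost <- simulate_gene_family(st, dup_spec = list(list(clade = clade, name = "alpha")),
                               loss_spec = list(list(copy = "alpha", species = clade[1])))
  expect_false(paste0(clade[1], "@alpha") %in% lost$gene_tree$tip.label)
})

test_that("codon simulation respects class proportions and plants diagnostics", {
  set.seed(1); tr <- ape::rtree(6); tr$edge.length <- pmax(tr$edge.length, 0.1) * 0.4
  fg <- pick_subclade(tr, 2, 4)
  sim <- simulate_codon_alignment(
    tr, list(model = "A", kappa = 2, omega0 = 0.1, omega2 = 5,
             p0 = 0.45, p1 = 0.45, n_codons = 500),
    foreground_clade = fg,
    diagnostic_spec = list(list(site = 10, cladeA_residue = "P", cladeB_residue = "N")),
    seed = 9)
  # ~10% of sites in the positively selected classes (binomial expectation)
  n_sel <- sum(sim$site_classes %in% 3:4)
  expect_gt(n_sel, 25); expect_lt(n_sel, 80)
  # no stop codons ever emitted
  m <- do.call(rbind, strsplit(as.character(sim$caln), "(?<=...)", perl = TRUE))
  expect_false(any(m %in% c("TAA", "TAG", "TGA")))
  # diagnostic column invariant per clade
  prot <- unclass(sim$protein)
  colA <- unique(prot[fg, 10]); colB <- unique(prot[setdiff(rownames(prot), fg), 10])
  expect_identical(colA, "P"); expect_identical(colB, "N")
  # omega2 = 1 everywhere means no truly selected site
  sim0 <- simulate_codon_alignment(
    tr, list(model = "A", kappa = 2, omega0 = 0.1, omega2 = 1,
             p0 = 0.45, p1 = 0.45, n_codons = 50),
    foreground_clade = fg, seed = 2)
  expect_length(sim0$selected_sites, 0L)
})

test_that("cluster annotations place focal and intervening genes as specified", {
  ann <- make_cluster_annotation(list(chromosome = "chr2",
                                      focal_ids = c("gA", "gB"),
                                      distance = 50000, n_intervening = 1))
  expect_equal(nrow(ann), 3L)
  rep <- gene_clusters(ann, c("gA", "gB"), 50000)
  expect_equal(rep$distance, 50000)
  expect_equal(rep$intervening_genes, 1L)
  adj <- make_cluster_annotation(list(chromosome = "c", focal_ids = c("x", "y"),
                                      distance = 0, n_intervening = 0))
  expect_equal(gene_clusters(adj, c("x", "y"))$distance, 0)
  expect_error(make_cluster_annotation(list(chromosome = "c", focal_ids = c("x", "y"),
                                            distance = 1000, n_intervening = 5)),
               "packing")
})

test_that("the full scenario is deterministic given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(simulate_scenario(seed = 7), d1)
  write_scenario(simulate_scenario(seed = 7), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different stream leaves earlier stages untouched: species tree equal
  # under the same master seed regardless of later config tweaks
  a <- simulate_scenario(seed = 7, config = list(n_decoys = 6L))
  b <- simulate_scenario(seed = 7)
  expect_identical(ape::write.tree(a$species_tree), ape::write.tree(b$species_tree))
  expect_identical(as.character(a$cds), as.character(b$cds))
})
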