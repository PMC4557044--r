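test_that("LCA reconciliation matches forced examples", {
  st <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  # gene tree congruent with the species tree: no duplications
  g0 <- ape::read.tree(text = "((A@1:1,B@1:1):1,C@1:2);")
  expect_equal(lca_reconcile(g0, st)$n_duplications, 0L)
  # ((A1,B1),(A2,B2)): one duplication at the gene root mapped to MRCA(A,B)
  g1 <- ape::read.tree(text = "(((A@1:1,B@1:1):.5,(A@2:1,B@2:1):.5):1,C@1:2);")
  rec <- lca_reconcile(g1, st)
  expect_equal(rec$n_duplications, 1L)
  expect_equal(rec$placements$species_node, ape::getMRCA(st, c("A", "B")))
  expect_error(lca_reconcile(ape::read.tree(text = "((A@1:1,Z@1:1):1,C@1:1);"), st),
               "unknown species")
})

test_that("duplication sets equal a brute-force per-node oracle on random pairs", {
  for (seed in 1:60) {
    pair <- random_recon_pair(seed)
    rec <- lca_reconcile(pair$gene, pair$species)
    expect_identical(sort(rec$duplication_nodes),
                     sort(oracle_reconcile_dups(pair$gene, pair$species)),
                     info = paste("seed", seed))
    # monotonicity: each node's mapping is ancestral-or-equal to its children's
    anc <- c(list(NULL), lapply(2:(length(pair$species$tip.label) + pair$species$Nnode),
                                function(v) phangorn::Ancestors(pair$species, v)))
    for (e in seq_len(nrow(pair$gene$edge))) {
      p <- rec$lca_map[pair$gene$edge[e, 1]]
      ch <- rec$lca_map[pair$gene$edge[e, 2]]
      expect_true(p == ch || p %in% phangorn::Ancestors(pair$species, ch))
    }
  }
})

test_that("clade duplication counts partition and match planted families", {
  st <- simulate_species_tree(10, 1, seed = 4)
  clade <- st$tip.label[unlist(phangorn::Descendants(st, ape::getMRCA(st, st$tip.label[1:3]), "tips"))]
  fam <- simulate_gene_family(st, dup_spec = list(
    list(clade = clade, name = "alpha"),
    list(clade = clade, name = "alpha2", parent_copy = "alpha"),
    list(clade = clade, name = "alpha3", parent_copy = "alpha2")))
  rec <- lca_reconcile(fam$gene_tree, st)
  expect_equal(rec$n_duplications, 3L)
  # the whole family spans all three duplications; the alpha clade (below
  # the first split) contains the two nested ones
  expect_equal(count_clade_duplications(rec, fam$gene_tree$tip.label), 3L)
  alpha_tips <- fam$gene_tree$tip.label[grepl("@alpha", fam$gene_tree$tip.label)]
  expect_equal(count_clade_duplications(rec, alpha_tips), 2L)
  # no duplication below any single copy subtree of the nested chain
  a3 <- fam$gene_tree$tip.label[grepl("@alpha3", fam$gene_tree$tip.label)]
  expect_equal(count_clade_duplications(rec, a3), 0L)
})

test_that("presence matrices attach traits and reproduce the published pattern", {
  # occurrence lists shaped like the reported DODA pattern: beta in 15/15
  # anthocyanic species, alpha in exactly one
  species <- sprintf("an%02d", 1:15)
  alpha_tips <- "an07@alpha"
  beta_tips <- paste0(species, "@beta")
  gt <- ape::rtree(16, tip.label = c(alpha_tips, beta_tips))
  traits <- setNames(rep("anthocyanin", 15), species)
  pm <- presence_matrix(gt, list(alpha = alpha_tips, beta = beta_tips),
                        species, traits = traits)
  expect_equal(sum(pm$beta), 15L)
  expect_equal(sum(pm$alpha), 1L)
  expect_true(pm$alpha[pm$species == "an07"])
  la <- loss_asymmetry(pm, "alpha", "beta", "anthocyanin")
  expect_equal(unname(la$table[1, ]), c(1, 14))
  expect_equal(unname(la$table[2, ]), c(15, 0))
  expect_equal(la$p_value, oracle_fisher_two_sided(la$table), tolerance = 1e-12)
  # species absent from the gene tree get an all-false row
  pm2 <- presence_matrix(gt, list(alpha = alpha_tips, beta = beta_tips),
                         c(species, "ghost"), traits = c(traits, ghost = "betalain"))
  expect_false(any(unlist(pm2[pm2$species == "ghost", c("alpha", "beta")])))
  expect_error(presence_matrix(gt, list(a = alpha_tips, b = c(alpha_tips, beta_tips)),
                               species), "overlap")
})

test_that("the exact loss-asymmetry test agrees with hypergeometric enumeration", {
  cases <- list(rbind(c(0, 15), c(15, 0)), rbind(c(3, 5), c(6, 2)),
                rbind(c(4, 4), c(4, 4)))
  for (tab in cases) {
    dimnames(tab) <- list(c("a", "b"), c("present", "absent"))
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_two_sided(tab),
                 tolerance = 1e-9)
  }
  # identical columns: p = 1
  pm <- data.frame(species = c("x", "y"), a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                   trait = "anthocyanin")
  expect_equal(loss_asymmetry(pm, "a", "b", "anthocyanin")$p_value, 1)
  expect_error(loss_asymmetry(pm, "a", "b", "betalain"), "no species")
})
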