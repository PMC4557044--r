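test_that("the GY94 generator has the defining structural properties", {
  pi_ <- rep(1 / 61, 61)
  Q <- codon_rate_matrix(2.5, 0.4)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_equal(-sum(pi_ * diag(Q)), 1, tolerance = 1e-12)       # unit rate
  D <- diag(pi_) %*% Q
  expect_equal(max(abs(D - t(D))), 0, tolerance = 1e-14)        # reversible
  # multi-nucleotide changes are forbidden
  expect_equal(Q["AAA", "ACC"], 0)
  expect_equal(Q["ATG", "GCA"], 0)
  # kappa = omega = 1, equal frequencies: all allowed changes share one rate
  Q1 <- codon_rate_matrix(1, 1, normalize = FALSE)
  off <- Q1[row(Q1) != col(Q1)]
  expect_setequal(round(unique(off), 12), round(c(0, 1 / 61), 12))
  # random parameter draws keep detailed balance
  set.seed(2)
  for (i in 1:3) {
    pr <- stats::runif(61); pr <- pr / sum(pr)
    Qr <- codon_rate_matrix(stats::runif(1, 0.5, 5), stats::runif(1, 0, 2), pr)
    Dr <- diag(pr) %*% Qr
    expect_equal(max(abs(Dr - t(Dr))), 0, tolerance = 1e-12)
  }
})

test_that("transition matrices are stochastic and satisfy Chapman-Kolmogorov", {
  pi_ <- rep(1 / 61, 61)
  Q <- codon_rate_matrix(2, 0.3)
  eig <- radphy:::codon_eigen(Q, pi_)
  for (t in c(0.1, 0.7, 2)) {
    P <- radphy:::codon_P(eig, t)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
  P1 <- radphy:::codon_P(eig, 0.3); P2 <- radphy:::codon_P(eig, 0.5)
  expect_equal(P1 %*% P2, radphy:::codon_P(eig, 0.8), tolerance = 1e-10)
})

test_that("degenerate and nested cases reduce exactly", {
  # single invariant codon column on a zero-length star tree: logL = log pi
  tree <- ape::read.tree(text = "(A:0,B:0,C:0);")
  caln <- structure(c(A = "ATG", B = "ATG", C = "ATG"),
                    class = "radphy_codon_alignment")
  expect_equal(site_model_loglik(tree, caln, "M0", list(kappa = 2, omega = 1),
                                 codon_freqs = "equal"),
               log(1 / 61), tolerance = 1e-10)
  # nesting identities on a 3-taxon toy
  set.seed(8); tr <- ape::rtree(3); tr$edge.length <- pmax(tr$edge.length, 0.2)
  sim <- simulate_codon_alignment(tr, list(model = "M0", kappa = 2, omega = 0.5,
                                           n_codons = 20), seed = 3)
  p_m1a <- list(kappa = 1.7, omega0 = 0.25, p0 = 0.6)
  ll_m1a <- site_model_loglik(tr, sim$caln, "M1a", p_m1a, codon_freqs = "equal")
  # M2a with p2 = 0 equals M1a at the shared parameters
  ll_m2a <- site_model_loglik(tr, sim$caln, "M2a",
                              list(kappa = 1.7, omega0 = 0.25, omega2 = 4,
                                   p0 = 0.6, p1 = 0.4), codon_freqs = "equal")
  expect_equal(ll_m2a, ll_m1a, tolerance = 1e-9)
  # model A with omega0 = omega2 = 1 collapses every class to neutral:
  # equal to M0 with omega = 1
  fg <- clade_edges(tr, tr$tip.label[1])
  pa <- list(kappa = 1.7, omega0 = 1, omega2 = 1, p0 = 0.3, p1 = 0.2)
  expect_equal(branch_site_loglik(tr, sim$caln, fg, pa, codon_freqs = "equal"),
               site_model_loglik(tr, sim$caln, "M0",
                                 list(kappa = 1.7, omega = 1),
                                 codon_freqs = "equal"),
               tolerance = 1e-9)
  # with p2 = 0 model A equals M1a at the shared parameters
  pa2 <- list(kappa = 1.7, omega0 = 0.25, omega2 = 6, p0 = 0.6 - 1e-12, p1 = 0.4 - 1e-12)
  expect_equal(branch_site_loglik(tr, sim$caln, fg, pa2, codon_freqs = "equal"),
               ll_m1a, tolerance = 1e-6)
  expect_error(branch_site_loglik(tr, sim$caln, integer(0), pa), "empty")
})

test_that("site-model likelihoods equal an independent series-expansion oracle", {
  pi_ <- rep(1 / 61, 61)
  two <- ape::read.tree(text = "(A:0.2,B:0.4);")
  caln2 <- structure(c(A = "ATGAAACCC", B = "ATGAAGCCA"),
                     class = "radphy_codon_alignment")
  # M0
  p0 <- list(kappa = 2, omega = 0.5)
  expect_equal(site_model_loglik(two, caln2, "M0", p0, codon_freqs = "equal"),
               oracle_codon_mixture_loglik(two, caln2,
                                           radphy:::model_site_classes("M0", p0),
                                           2, pi_),
               tolerance = 1e-8)
  # M1a and M2a mixtures
  p1 <- list(kappa = 1.5, omega0 = 0.2, p0 = 0.7)
  expect_equal(site_model_loglik(two, caln2, "M1a", p1, codon_freqs = "equal"),
               oracle_codon_mixture_loglik(two, caln2,
                                           radphy:::model_site_classes("M1a", p1),
                                           1.5, pi_),
               tolerance = 1e-8)
  p2 <- list(kappa = 1.5, omega0 = 0.2, omega2 = 3, p0 = 0.5, p1 = 0.3)
  expect_equal(site_model_loglik(two, caln2, "M2a", p2, codon_freqs = "equal"),
               oracle_codon_mixture_loglik(two, caln2,
                                           radphy:::model_site_classes("M2a", p2),
                                           1.5, pi_),
               tolerance = 1e-8)
  # branch-site model A on a 3-taxon toy with one foreground edge
  three <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4);")
  caln3 <- structure(c(A = "ATGAAA", B = "ATGAAG", C = "ATGCAA"),
                     class = "radphy_codon_alignment")
  fg <- which(three$tip.label == "A")
  pA <- list(kappa = 2, omega0 = 0.1, omega2 = 4, p0 = 0.4, p1 = 0.4)
  expect_equal(branch_site_loglik(three, caln3, fg, pA, codon_freqs = "equal"),
               oracle_codon_mixture_loglik(three, caln3,
                                           radphy:::model_site_classes("A", pA),
                                           2, pi_, fg_children = fg),
               tolerance = 1e-8)
})

test_that("likelihoods are invariant under compatible re-rootings", {
  tr <- ape::read.tree(
    text = "((A:0.2,B:0.3):0.15,(C:0.2,(D:0.25,E:0.2):0.1):0.2);")
  sim <- simulate_codon_alignment(tr, list(model = "M0", kappa = 2, omega = 0.4,
                                           n_codons = 40), seed = 5)
  p <- list(kappa = 2, omega0 = 0.3, p0 = 0.6)
  base <- site_model_loglik(tr, sim$caln, "M1a", p, codon_freqs = "equal")
  nodeA <- which(tr$tip.label == "A")
  re <- phytools::reroot(tr, nodeA,
                         position = tr$edge.length[tr$edge[, 2] == nodeA] / 2)
  expect_equal(site_model_loglik(re, sim$caln, "M1a", p, codon_freqs = "equal"),
               base, tolerance = 1e-8)
  # model A: invariant only under re-rootings that preserve the foreground
  # edge set -- here the foreground is D's pendant edge, untouched when the
  # root moves onto A's edge (the dissolved root merges background edges)
  fgt <- "D"
  fg1 <- clade_edges(tr, fgt)
  pa <- list(kappa = 2, omega0 = 0.3, omega2 = 3, p0 = 0.5, p1 = 0.3)
  b1 <- branch_site_loglik(tr, sim$caln, fg1, pa, codon_freqs = "equal")
  fg2 <- clade_edges(re, fgt)
  expect_equal(branch_site_loglik(re, sim$caln, fg2, pa, codon_freqs = "equal"),
               b1, tolerance = 1e-8)
})

test_that("the LRT is clamped, chi-squared calibrated, and guards nesting", {
  f1 <- structure(list(model = "M1a", logLik = -100), class = "radphy_codon_fit")
  f2 <- structure(list(model = "M2a", logLik = -100), class = "radphy_codon_fit")
  out <- lrt(f1, f2)
  expect_equal(out$statistic, 0); expect_equal(out$p_value, 1)
  f3 <- structure(list(model = "M2a", logLik = -100 + 5.991465 / 2),
                  class = "radphy_codon_fit")
  expect_equal(lrt(f1, f3)$p_value, 0.05, tolerance = 1e-4)
  expect_equal(lrt(f1, f3)$df, 2L)
  fn <- structure(list(model = "A_null", logLik = -50), class = "radphy_codon_fit")
  fa <- structure(list(model = "A", logLik = -48), class = "radphy_codon_fit")
  mix <- lrt(fn, fa, mixture = TRUE)
  expect_equal(mix$p_value, 0.5 * stats::pchisq(4, 1, lower.tail = FALSE))
  expect_error(lrt(f2, f1), "not nested")
})

test_that("empirical Bayes posteriors are proper and ignore invariant columns", {
  set.seed(10); tr <- ape::rtree(4); tr$edge.length <- pmax(tr$edge.length, 0.3)
  fgt <- tr$tip.label[1]
  sim <- simulate_codon_alignment(tr, list(model = "A", kappa = 2, omega0 = 0.1,
                                           omega2 = 6, p0 = 0.4, p1 = 0.4,
                                           n_codons = 60),
                                  foreground_clade = fgt, seed = 2)
  # plant one invariant column
  m <- radphy:::codon_rows_matrix(sim$caln); m[, 1] <- "ATG"
  caln <- radphy:::codon_matrix_to_caln(m)
  fit <- fit_codon_model(tr, caln, "A", foreground_edges = clade_edges(tr, fgt),
                         codon_freqs = "equal", n_starts = 1)
  for (method in c("NEB", "BEB")) {
    post <- eb_site_posteriors(fit, method = method)
    cls <- as.matrix(post[, grepl("^class", names(post))])
    expect_equal(rowSums(cls), rep(1, nrow(cls)), tolerance = 1e-8)
    expect_true(all(post$p_selected >= 0 & post$p_selected <= 1))
    # the invariant column carries no evidence of positive selection
    expect_lt(post$p_selected[1], 0.95)
    expect_identical(attr(post, "method"), method)
  }
})

test_that("fits are deterministic given the seed and improve on their starts", {
  set.seed(3); tr <- ape::rtree(4); tr$edge.length <- pmax(tr$edge.length, 0.2)
  sim <- simulate_codon_alignment(tr, list(model = "M0", kappa = 2, omega = 0.3,
                                           n_codons = 80), seed = 6)
  fa <- fit_codon_model(tr, sim$caln, "M1a", codon_freqs = "equal",
                        n_starts = 2, seed = 42)
  fb <- fit_codon_model(tr, sim$caln, "M1a", codon_freqs = "equal",
                        n_starts = 2, seed = 42)
  expect_identical(fa$logLik, fb$logLik)
  expect_identical(fa$params, fb$params)
  # the alternative refitted from the null's optimum never scores lower
  m2 <- fit_codon_model(tr, sim$caln, "M2a", codon_freqs = "equal",
                        n_starts = 1, start = nested_start_m2a(fa$params))
  expect_gte(m2$logLik, fa$logLik - 1e-3)
})
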