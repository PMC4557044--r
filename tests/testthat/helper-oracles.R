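# Independent oracles used across the suite. Each is deliberately written
# from first principles, by a different route than the implementation it
# checks: exhaustive enumeration for pruning likelihoods and reconciliation,
# a series-expansion matrix exponential for codon models, a plain
# dynamic-programming matrix for local alignment, and hypergeometric
# enumeration for the exact test.

# ---- Mk1: exhaustive sum over internal-node state assignments -----------
oracle_mk1_loglik <- function(tree, traits, rate) {
  ntip <- length(tree$tip.label)
  tipst <- match(traits[tree$tip.label], c("anthocyanin", "betalain"))
  grids <- expand.grid(rep(list(1:2), tree$Nnode))
  tot <- 0
  for (r in seq_len(nrow(grids))) {
    s <- c(tipst, as.integer(grids[r, ]))
    p <- 0.5
    for (e in seq_len(nrow(tree$edge))) {
      a <- s[tree$edge[e, 1]]; b <- s[tree$edge[e, 2]]
      if (is.na(b)) next  # missing tip: sum over its states = factor 1
      P <- mk1_transition(rate, tree$edge.length[e])
      if (is.na(a)) stop("internal NA state")
      p <- p * P[a, b]
    }
    tot <- tot + p
  }
  # missing tips handled by dropping their factor only if the tip has no
  # descendants (always true); states of missing tips summed out give 1
  log(tot)
}

oracle_mk1_node_posterior <- function(tree, traits, rate, node) {
  ntip <- length(tree$tip.label)
  tipst <- match(traits[tree$tip.label], c("anthocyanin", "betalain"))
  grids <- expand.grid(rep(list(1:2), tree$Nnode))
  acc <- c(0, 0)
  for (r in seq_len(nrow(grids))) {
    s <- c(tipst, as.integer(grids[r, ]))
    p <- 0.5
    for (e in seq_len(nrow(tree$edge))) {
      b <- s[tree$edge[e, 2]]
      if (is.na(b)) next
      P <- mk1_transition(rate, tree$edge.length[e])
      p <- p * P[s[tree$edge[e, 1]], b]
    }
    k <- s[node]
    acc[k] <- acc[k] + p
  }
  acc / sum(acc)
}

# ---- codon models: independent likelihood via series-expansion expm -----
oracle_codon_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc_ <- Biostrings::GENETIC_CODE
    sense <- names(gc_)[gc_ != "*"]
    cache <<- list(sense = sense, aa = unname(gc_[sense]))
    cache
  }
})

oracle_codon_Q <- function(kappa, omega, pi_) {
  oc <- oracle_codon_tables()
  n <- length(oc$sense)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ci <- strsplit(oc$sense[i], "")[[1]]; cj <- strsplit(oc$sense[j], "")[[1]]
    d <- which(ci != cj)
    if (length(d) != 1) next
    ts <- paste0(sort(c(ci[d], cj[d])), collapse = "") %in% c("AG", "CT")
    ns <- oc$aa[i] != oc$aa[j]
    Q[i, j] <- pi_[j] * (if (ts) kappa else 1) * (if (ns) omega else 1)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

oracle_expm <- function(M, terms = 80) {
  R <- diag(nrow(M)); term <- diag(nrow(M))
  for (k in seq_len(terms)) {
    term <- term %*% M / k
    R <- R + term
  }
  R
}

# Mixture log-likelihood for up-to-3-taxon codon toys: explicit sum over
# root (= internal node) states, matching the implementation's scaling
# convention (mixture-average rate with background omegas normalised to 1).
oracle_codon_mixture_loglik <- function(tree, caln, classes, kappa, pi_,
                                        fg_children = integer(0)) {
  oc <- oracle_codon_tables()
  rate_of <- function(w) {
    Q <- oracle_codon_Q(kappa, w, pi_)
    -sum(pi_ * diag(Q))
  }
  scale <- sum(vapply(classes, function(cl) cl$prop * rate_of(cl$bg), 0))
  m <- vapply(names(caln), function(id) {
    s <- caln[[id]]
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }, character(nchar(caln[[1]]) / 3))
  m <- t(m)  # rows taxa, cols sites
  if (nchar(caln[[1]]) == 3) m <- matrix(m, ncol = 1, dimnames = list(names(caln), NULL))
  ntip <- length(tree$tip.label)
  stopifnot(tree$Nnode <= 2)
  total <- 0
  for (s in seq_len(ncol(m))) {
    per_class <- vapply(classes, function(cl) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
        w <- if (tree$edge[e, 2] %in% fg_children) cl$fg else cl$bg
        oracle_expm(oracle_codon_Q(kappa, w, pi_) / scale * tree$edge.length[e])
      })
      inner <- (ntip + 1):(ntip + tree$Nnode)
      states <- expand.grid(rep(list(seq_along(oc$sense)), tree$Nnode))
      tot <- 0
      for (r in seq_len(nrow(states))) {
        assign_ <- integer(ntip + tree$Nnode)
        assign_[inner] <- as.integer(states[r, ])
        for (i in seq_len(ntip))
          assign_[i] <- match(m[tree$tip.label[i], s], oc$sense)
        p <- pi_[assign_[ntip + 1]]
        for (e in seq_len(nrow(tree$edge)))
          p <- p * Ps[[e]][assign_[tree$edge[e, 1]], assign_[tree$edge[e, 2]]]
        tot <- tot + p
      }
      tot
    }, 0)
    total <- total + log(sum(vapply(classes, `[[`, 0, "prop") * per_class))
  }
  total
}

# ---- reconciliation: per-node LCA check done independently --------------
oracle_reconcile_dups <- function(gene_tree, species_tree, delim = "@") {
  ntip <- length(gene_tree$tip.label)
  tips_below <- function(tr, v) {
    if (v <= length(tr$tip.label)) tr$tip.label[v]
    else tr$tip.label[unlist(phangorn::Descendants(tr, v, "tips"))]
  }
  smap <- function(species_set) {
    idx <- which(species_tree$tip.label %in% species_set)
    if (length(idx) == 1) idx else ape::getMRCA(species_tree, species_tree$tip.label[idx])
  }
  dups <- integer(0)
  for (v in (ntip + 1):(ntip + gene_tree$Nnode)) {
    own <- smap(unique(tip_species(tips_below(gene_tree, v), delim)))
    kids <- gene_tree$edge[gene_tree$edge[, 1] == v, 2]
    kid_maps <- vapply(kids, function(k)
      smap(unique(tip_species(tips_below(gene_tree, k), delim))), 0L)
    if (any(kid_maps == own)) dups <- c(dups, v)
  }
  dups
}

# random gene/species tree pair: species tree + random gene tips labelled
# species@copy (duplicate species allowed)
random_recon_pair <- function(seed) {
  set.seed(seed)
  n_sp <- sample(3:6, 1)
  st <- ape::rtree(n_sp, tip.label = paste0("S", seq_len(n_sp)))
  n_gene <- sample(3:8, 1)
  sp <- sample(st$tip.label, n_gene, replace = TRUE)
  labs <- paste0(sp, "@g", seq_len(n_gene))
  gt <- ape::rtree(n_gene, tip.label = labs)
  list(gene = gt, species = st)
}

# ---- local alignment: plain Smith-Waterman DP ---------------------------
oracle_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
oracle_smith_waterman <- function(q, t, mat, gap_open, gap_ext) {
  qs <- strsplit(q, "")[[1]]; ts <- strsplit(t, "")[[1]]
  n <- length(qs); m <- length(ts)
  H <- matrix(0, n + 1, m + 1); E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
    F_[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F_[i - 1, j] - gap_ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[qs[i - 1], ts[j - 1]], E[i, j], F_[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# ---- Fisher exact test by hypergeometric enumeration --------------------
oracle_fisher_two_sided <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}

# a proper (non-root) clade of the tree with size within [lo, hi]
pick_subclade <- function(tree, lo = 2L, hi = 5L) {
  ntip <- length(tree$tip.label)
  for (v in (ntip + 2L):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[unlist(phangorn::Descendants(tree, v, "tips"))]
    if (length(tips) >= lo && length(tips) <= hi) return(tips)
  }
  stop("no suitable subclade")
}

# ---- small fixtures -----------------------------------------------------
balanced_tree6 <- function() {
  ape::read.tree(text = "(((A:0.2,B:0.3):0.15,(C:0.25,D:0.1):0.2):0.1,(E:0.3,F:0.4):0.2);")
}

random_trait_tree <- function(seed, n = 6) {
  set.seed(seed)
  tr <- ape::rtree(n)
  states <- sample(c("anthocyanin", "betalain", "missing"), n,
                   replace = TRUE, prob = c(0.45, 0.45, 0.1))
  list(tree = tr, traits = setNames(states, tr$tip.label))
}
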