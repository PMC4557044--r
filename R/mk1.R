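# One-rate symmetric binary-trait model (Mk1): closed-form transition
# probabilities, Felsenstein pruning over a rooted tree with root prior
# (1/2, 1/2), maximum-likelihood rate estimation, and marginal ancestral
# state posteriors by the standard two-pass (re-rooting) scheme.
# State order throughout: 1 = anthocyanin, 2 = betalain; OTUs coded
# "missing" contribute partial likelihood (1, 1).

MK1_STATES <- c("anthocyanin", "betalain")

#' Mk1 transition probability matrix
#'
#' With one symmetric rate `r`, `P_same = (1 + e^(-2rt))/2` and
#' `P_diff = (1 - e^(-2rt))/2`.
#'
#' @param rate non-negative rate.
#' @param t non-negative time (branch length).
#' @return 2x2 matrix.
#' @export
mk1_transition <- function(rate, t) {
  if (rate < 0 || t < 0) stop("rate and time must be non-negative")
  e <- exp(-2 * rate * t)
  same <- (1 + e) / 2
  diff <- (1 - e) / 2
  matrix(c(same, diff, diff, same), 2, 2,
         dimnames = list(MK1_STATES, MK1_STATES))
}

# Tip partial likelihoods: 2-column matrix in gene-tree tip order.
mk1_tip_partials <- function(tree, traits) {
  absent <- setdiff(tree$tip.label, names(traits))
  if (length(absent)) stop("tip missing from trait table: ", absent[1])
  st <- traits[tree$tip.label]
  L <- matrix(1, length(st), 2)
  L[st == "anthocyanin", 2] <- 0
  L[st == "betalain", 1] <- 0
  L
}

# Pruning pass: returns list(partials = (ntip+nnode) x 2, logscale).
mk1_down_pass <- function(tree, tipL, rate) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  part <- matrix(1, nn, 2)
  part[seq_len(ntip), ] <- tipL
  scale_log <- 0
  ord <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(ord$edge))) {
    p <- ord$edge[r, 1L]; ch <- ord$edge[r, 2L]
    P <- mk1_transition(rate, ord$edge.length[r])
    part[p, ] <- part[p, ] * as.numeric(P %*% part[ch, ])
  }
  part
}

#' Mk1 log-likelihood of a trait table on a tree
#'
#' Felsenstein pruning over the rooted tree with root prior (1/2, 1/2);
#' `"missing"` states contribute partial likelihood (1, 1).
#'
#' @param tree rooted phylo tree.
#' @param traits named states (`anthocyanin`/`betalain`/`missing`) covering
#'   every tip.
#' @param rate Mk1 rate.
#' @return Log-likelihood.
#' @export
mk1_loglik <- function(tree, traits, rate) {
  tipL <- mk1_tip_partials(tree, traits)
  part <- mk1_down_pass(tree, tipL, rate)
  root <- length(tree$tip.label) + 1L
  log(sum(0.5 * part[root, ]))
}

#' Fit the Mk1 rate by maximum likelihood
#'
#' Bounded one-dimensional optimization of the rate on a log scale over
#' `[1e-8, 1e3]`. When every non-missing tip carries the same state the
#' likelihood is monotone decreasing in the rate and the fit sits at the
#' lower bound (flagged with a warning).
#'
#' @param tree rooted phylo tree.
#' @param traits trait table.
#' @param lower,upper rate bounds.
#' @param tol optimizer tolerance (on log-rate).
#' @return List of class `"radphy_mk1"`: `rate`, `logLik`, `neg_logLik`,
#'   `boundary` flag, `node_posteriors` (see [marginal_asr()]).
#' @export
fit_mk1 <- function(tree, traits, lower = 1e-8, upper = 1e3, tol = 1e-8) {
  obs <- traits[tree$tip.label]
  states <- unique(obs[obs != "missing"])
  boundary <- FALSE
  if (length(states) <= 1L) {
    warning("all non-missing tips share one state; rate MLE at lower bound")
    rate <- lower
    boundary <- TRUE
  } else {
    opt <- stats::optimize(function(lr) -mk1_loglik(tree, traits, exp(lr)),
                           c(log(lower), log(upper)), tol = tol)
    rate <- exp(opt$minimum)
    if (opt$minimum < log(lower) + 1e-6 || opt$minimum > log(upper) - 1e-6)
      boundary <- TRUE
  }
  ll <- mk1_loglik(tree, traits, rate)
  structure(list(rate = rate, logLik = ll, neg_logLik = -ll,
                 boundary = boundary,
                 node_posteriors = marginal_asr(tree, traits, rate)),
            class = "radphy_mk1")
}

#' @export
print.radphy_mk1 <- function(x, ...) {
  cat(sprintf("Mk1 fit: rate = %.8g, -log L = %.8f%s\n",
              x$rate, x$neg_logLik,
              if (x$boundary) " (boundary optimum)" else ""))
  invisible(x)
}

#' Marginal ancestral state posteriors under Mk1
#'
#' For each internal node, the posterior probability of each state given
#' all tip data, via the standard two-pass (re-rooting) computation: the
#' downward partials are combined with the likelihood of the rest of the
#' tree conditional on the node's state.
#'
#' @param tree rooted phylo tree.
#' @param traits trait table.
#' @param rate Mk1 rate (fitted or supplied).
#' @return Matrix (one row per internal node, in node-number order) with
#'   columns `anthocyanin`, `betalain`, rows summing to 1.
#' @export
marginal_asr <- function(tree, traits, rate) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  tipL <- mk1_tip_partials(tree, traits)
  down <- mk1_down_pass(tree, tipL, rate)
  # "up" partials: U[v, s] = likelihood of data outside v's clade given
  # state s at v, including the root prior.
  up <- matrix(NA_real_, nn, 2)
  up[root, ] <- c(0.5, 0.5)
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
  elen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (r in seq_len(nrow(edges))) {
    p <- edges[r, 1L]; v <- edges[r, 2L]
    sibs <- tree$edge[, 2L][tree$edge[, 1L] == p]
    sibs <- sibs[sibs != v]
    contrib <- up[p, ]
    for (s in sibs) {
      Ps <- mk1_transition(rate, tree$edge.length[tree$edge[, 2L] == s])
      contrib <- contrib * as.numeric(Ps %*% down[s, ])
    }
    Pv <- mk1_transition(rate, elen[r])
    up[v, ] <- as.numeric(t(Pv) %*% contrib)
  }
  post <- down * up
  post <- post / rowSums(post)
  out <- post[root:nn, , drop = FALSE]
  colnames(out) <- MK1_STATES
  rownames(out) <- as.character(root:nn)
  out
}
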