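# GY94-style codon substitution models over the 61 sense codons of the
# standard genetic code: M0, the site models M1a ("nearly neutral") and
# M2a ("positive selection"), and branch-site model A with an a priori
# foreground branch set. Likelihoods use Felsenstein pruning with
# eigendecomposition-based transition matrices; inference adds likelihood
# ratio tests and naive / Bayes empirical Bayes site posteriors.

# ---- genetic code machinery --------------------------------------------

codon_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc_ <- Biostrings::GENETIC_CODE
    sense <- names(gc_)[gc_ != "*"]
    aa <- unname(gc_[sense])
    n <- length(sense)  # 61
    bases <- lapply(strsplit(sense, ""), identity)
    bmat <- do.call(rbind, bases)
    single <- matrix(FALSE, n, n)
    transition <- matrix(FALSE, n, n)
    nonsyn <- matrix(FALSE, n, n)
    is_ts <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
    for (i in seq_len(n)) {
      d <- bmat != matrix(bmat[i, ], n, 3, byrow = TRUE)
      one <- rowSums(d) == 1L
      single[i, one] <- TRUE
      js <- which(one)
      pos <- apply(d[js, , drop = FALSE], 1L, which)
      for (k in seq_along(js)) {
        j <- js[k]; p <- pos[k]
        transition[i, j] <- is_ts(bmat[i, p], bmat[j, p])
        nonsyn[i, j] <- aa[i] != aa[j]
      }
    }
    cache <<- list(codons = sense, aa = aa, n = n, single = single,
                   transition = transition, nonsyn = nonsyn)
    cache
  }
})

sense_codons <- function() codon_tables()$codons

#' GY94 codon rate matrix
#'
#' Off-diagonal rate `q_ij` is zero for codon pairs differing at more than
#' one position and otherwise `pi_j`, multiplied by `kappa` for transitions
#' and by `omega` for nonsynonymous changes; rows sum to zero. With
#' `normalize = TRUE` the generator is rescaled so the expected number of
#' substitutions per codon site per unit time is 1 at stationarity. The
#' matrix is time-reversible (`pi_i q_ij = pi_j q_ji`).
#'
#' @param kappa transition/transversion ratio (> 0).
#' @param omega nonsynonymous/synonymous ratio (>= 0).
#' @param codon_freqs length-61 stationary codon frequencies (sum 1);
#'   default equal.
#' @param normalize rescale to unit expected rate.
#' @return 61x61 generator matrix with codon dimnames.
#' @export
codon_rate_matrix <- function(kappa, omega, codon_freqs = NULL, normalize = TRUE) {
  ct <- codon_tables()
  stopifnot(kappa > 0, omega >= 0)
  pi_ <- codon_freqs %||% rep(1 / ct$n, ct$n)
  if (length(pi_) != ct$n || abs(sum(pi_) - 1) > 1e-8)
    stop("codon_freqs must be 61 frequencies summing to 1")
  Q <- matrix(0, ct$n, ct$n, dimnames = list(ct$codons, ct$codons))
  Q[ct$single] <- rep(pi_, each = ct$n)[ct$single]
  Q[ct$single & ct$transition] <- Q[ct$single & ct$transition] * kappa
  Q[ct$single & ct$nonsyn] <- Q[ct$single & ct$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(pi_ * diag(Q))
    Q <- Q / mu
  }
  Q
}

# Expected substitution rate of the unnormalized GY94 generator, linear in
# omega: rate(omega) = r_syn(kappa) + omega * r_nonsyn(kappa).
codon_rate_parts <- function(kappa, pi_) {
  ct <- codon_tables()
  W <- matrix(pi_, ct$n, ct$n, byrow = TRUE)
  W[!ct$single] <- 0
  W[ct$single & ct$transition] <- W[ct$single & ct$transition] * kappa
  flux <- pi_ * W
  c(syn = sum(flux[ct$single & !ct$nonsyn]),
    nonsyn = sum(flux[ct$single & ct$nonsyn]))
}

# Symmetric eigendecomposition of a reversible generator; P(t) follows by
# exponentiating the eigenvalues.
codon_eigen <- function(Q, pi_) {
  s <- sqrt(pi_)
  B <- (s * Q) %*% diag(1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / s, Uinv = t(e$vectors) * rep(s, each = length(s)),
       values = e$values)
}

codon_P <- function(eig, t) {
  P <- (eig$U * rep(exp(eig$values * t), each = nrow(eig$U))) %*% eig$Uinv
  P[P < 0] <- 0
  P
}

# ---- alignment preparation ---------------------------------------------

#' F3x4 codon frequencies from a codon alignment
#'
#' Position-specific nucleotide frequencies multiplied across the three
#' codon positions, restricted and renormalized to the 61 sense codons.
#'
#' @param caln codon alignment.
#' @return Length-61 frequency vector.
#' @export
f3x4_freqs <- function(caln) {
  ct <- codon_tables()
  m <- codon_rows_matrix(caln)
  cells <- m[grepl("^[ACGT]{3}$", m)]
  if (!length(cells)) stop("no unambiguous codons in alignment")
  posfreq <- vapply(1:3, function(p) {
    tab <- table(factor(substring(cells, p, p), levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(cells)
  }, numeric(4))
  rownames(posfreq) <- c("A", "C", "G", "T")
  pi_ <- vapply(ct$codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    posfreq[b[1], 1] * posfreq[b[2], 2] * posfreq[b[3], 3]
  }, 0)
  pi_ <- pi_ + 1e-9  # keep strictly positive for the symmetric decomposition
  pi_ / sum(pi_)
}

# Codon alignment -> integer index matrix (rows tips, cols sites); NA for
# gaps / ambiguity codes, which act as missing data in the likelihood.
caln_to_indices <- function(caln) {
  ct <- codon_tables()
  m <- codon_rows_matrix(caln)
  if (any(m %in% ct$codons == FALSE & grepl("^[ACGT]{3}$", m)))
    stop("stop codon in alignment: ", m[grepl("^[ACGT]{3}$", m) & !(m %in% ct$codons)][1])
  idx <- matrix(match(m, ct$codons), nrow(m), ncol(m), dimnames = dimnames(m))
  idx
}

# ---- pruning ------------------------------------------------------------

# Precomputed traversal and site-pattern compression shared by every
# likelihood evaluation of one fit.
codon_prep <- function(tree, idx) {
  ord <- ape::reorder.phylo(tree, "postorder")
  key <- apply(idx, 2L, paste, collapse = ",")
  uq <- which(!duplicated(key))
  list(ntip = length(tree$tip.label),
       nn = length(tree$tip.label) + tree$Nnode,
       edge = ord$edge, edge.length = ord$edge.length,
       tip_row = match(tree$tip.label, rownames(idx)),
       idx_u = idx[, uq, drop = FALSE],
       map = match(key, key[uq]))
}

# Per-site log-likelihood given one transition matrix per postorder edge.
codon_site_loglik_onepass <- function(prep, P_edges, pi_) {
  ntip <- prep$ntip
  idx <- prep$idx_u
  S <- ncol(idx)
  part <- vector("list", prep$nn)
  logscale <- rep(0, S)
  check_scale <- prep$nn > 40L
  for (r in seq_len(nrow(prep$edge))) {
    p <- prep$edge[r, 1L]; ch <- prep$edge[r, 2L]
    P <- P_edges[[r]]
    if (ch <= ntip) {
      states <- idx[prep$tip_row[ch], ]
      if (anyNA(states)) {
        tmp <- matrix(1, nrow(P), S)
        ok <- !is.na(states)
        tmp[, ok] <- P[, states[ok], drop = FALSE]
      } else {
        tmp <- P[, states, drop = FALSE]
      }
    } else {
      tmp <- P %*% part[[ch]]
      part[ch] <- list(NULL)
    }
    part[[p]] <- if (is.null(part[[p]])) tmp else part[[p]] * tmp
    if (check_scale && isTRUE(max(part[[p]]) < 1e-120)) {
      sc <- apply(part[[p]], 2L, max)
      sc[sc == 0] <- 1
      part[[p]] <- sweep(part[[p]], 2L, sc, "/")
      logscale <- logscale + log(sc)
    }
  }
  L <- as.numeric(pi_ %*% part[[ntip + 1L]])
  log(L) + logscale
}

# Site classes of a model: list of (prop, omega_bg, omega_fg).
model_site_classes <- function(model, params) {
  with(params, switch(model,
    M0 = list(list(prop = 1, bg = omega, fg = omega)),
    M1a = list(list(prop = p0, bg = omega0, fg = omega0),
               list(prop = 1 - p0, bg = 1, fg = 1)),
    M2a = list(list(prop = p0, bg = omega0, fg = omega0),
               list(prop = p1, bg = 1, fg = 1),
               list(prop = 1 - p0 - p1, bg = omega2, fg = omega2)),
    A = ,
    A_null = {
      p2 <- 1 - p0 - p1
      list(list(prop = p0, bg = omega0, fg = omega0),
           list(prop = p1, bg = 1, fg = 1),
           list(prop = p2 * p0 / (p0 + p1), bg = omega0, fg = omega2),
           list(prop = p2 * p1 / (p0 + p1), bg = 1, fg = omega2))
    },
    stop("unknown model: ", model)))
}

# Per-class per-site log-likelihood matrix (classes x sites) plus class
# proportions. Branch lengths are interpreted as expected substitutions per
# codon site under the class mixture, using background omegas for the
# normalizing rate.
codon_class_site_logliks <- function(tree, idx, classes, kappa, pi_,
                                     foreground = integer(0),
                                     scale_rate = NULL, prep = NULL) {
  parts <- codon_rate_parts(kappa, pi_)
  if (is.null(scale_rate))
    scale_rate <- sum(vapply(classes, function(cl)
      cl$prop * (parts["syn"] + cl$bg * parts["nonsyn"]), 0))
  if (is.null(prep)) prep <- codon_prep(tree, idx)
  omegas <- sort(unique(unlist(lapply(classes, function(cl) c(cl$bg, cl$fg)))))
  eigs <- lapply(omegas, function(w)
    codon_eigen(codon_rate_matrix(kappa, w, pi_, normalize = FALSE) / scale_rate, pi_))
  names(eigs) <- as.character(omegas)
  is_fg <- prep$edge[, 2L] %in% as.integer(foreground)
  # transition matrices computed once per (omega, edge) and shared between
  # classes (model A reuses the background matrices across classes)
  needed <- lapply(seq_along(omegas), function(i) rep(FALSE, nrow(prep$edge)))
  names(needed) <- as.character(omegas)
  for (cl in classes) {
    needed[[as.character(cl$bg)]] <- needed[[as.character(cl$bg)]] | !is_fg
    needed[[as.character(cl$fg)]] <- needed[[as.character(cl$fg)]] | is_fg
  }
  Pcache <- lapply(as.character(omegas), function(w) {
    out <- vector("list", nrow(prep$edge))
    idxs <- which(needed[[w]])
    out[idxs] <- lapply(prep$edge.length[idxs], function(t) codon_P(eigs[[w]], t))
    out
  })
  names(Pcache) <- as.character(omegas)
  ll <- t(vapply(classes, function(cl) {
    P_edges <- vector("list", nrow(prep$edge))
    wchar <- ifelse(is_fg, as.character(cl$fg), as.character(cl$bg))
    for (r in seq_len(nrow(prep$edge))) P_edges[[r]] <- Pcache[[wchar[r]]][[r]]
    codon_site_loglik_onepass(prep, P_edges, pi_)
  }, numeric(ncol(prep$idx_u))))
  if (ncol(prep$idx_u) == 1L) ll <- matrix(ll, ncol = 1L)
  ll <- ll[, prep$map, drop = FALSE]
  list(ll = ll, props = vapply(classes, `[[`, 0, "prop"))
}

mixture_total_loglik <- function(cls) {
  mx <- apply(cls$ll, 2L, max)
  sum(log(colSums(cls$props * exp(sweep(cls$ll, 2L, mx, "-")))) + mx)
}

#' Log-likelihood of a site model (M0, M1a, M2a)
#'
#' Per-site likelihood is the proportion-weighted mixture over site
#' classes; sites are independent. Gap or ambiguous codons act as missing
#' data, but cleaned alignments (see [clean_codon_columns()]) are the
#' intended input.
#'
#' @param tree phylo tree whose tips match the alignment rows.
#' @param caln codon alignment.
#' @param model `"M0"`, `"M1a"` or `"M2a"`.
#' @param params list with `kappa` and, per model, `omega` (M0);
#'   `omega0`, `p0` (M1a); `omega0`, `omega2`, `p0`, `p1` (M2a).
#' @param codon_freqs `"equal"`, `"f3x4"`, or a 61-vector.
#' @return Total log-likelihood.
#' @export
site_model_loglik <- function(tree, caln, model = c("M0", "M1a", "M2a"),
                              params, codon_freqs = "f3x4") {
  model <- match.arg(model)
  pi_ <- resolve_codon_freqs(codon_freqs, caln)
  idx <- caln_to_indices(caln)[tree$tip.label, , drop = FALSE]
  cls <- codon_class_site_logliks(tree, idx, model_site_classes(model, params),
                                  params$kappa, pi_)
  mixture_total_loglik(cls)
}

#' Log-likelihood of branch-site model A
#'
#' Four site classes: 0 (`omega0` everywhere), 1 (neutral everywhere), 2a
#' (`omega0` background / `omega2` foreground) and 2b (neutral background /
#' `omega2` foreground), with proportions `p0`, `p1`,
#' `p2*p0/(p0+p1)`, `p2*p1/(p0+p1)` where `p2 = 1 - p0 - p1`.
#'
#' @param tree phylo tree.
#' @param caln codon alignment.
#' @param foreground_edges foreground branches, as the child-node numbers
#'   of their edges (see [clade_edges()]).
#' @param params list with `kappa`, `omega0`, `omega2`, `p0`, `p1`.
#' @param codon_freqs as in [site_model_loglik()].
#' @return Total log-likelihood.
#' @export
branch_site_loglik <- function(tree, caln, foreground_edges, params,
                               codon_freqs = "f3x4") {
  if (!length(foreground_edges)) stop("empty foreground branch set")
  pi_ <- resolve_codon_freqs(codon_freqs, caln)
  idx <- caln_to_indices(caln)[tree$tip.label, , drop = FALSE]
  cls <- codon_class_site_logliks(tree, idx, model_site_classes("A", params),
                                  params$kappa, pi_, foreground_edges)
  mixture_total_loglik(cls)
}

resolve_codon_freqs <- function(codon_freqs, caln) {
  if (is.numeric(codon_freqs)) return(codon_freqs)
  switch(codon_freqs,
         equal = rep(1 / 61, 61),
         f3x4 = f3x4_freqs(caln),
         stop("codon_freqs must be 'equal', 'f3x4' or a 61-vector"))
}

#' Branches within a clade, for foreground specification
#'
#' Resolves "all branches within" the clade spanned by `tips` to the
#' child-node numbers of those edges; `include_stem` adds the clade's stem
#' branch.
#'
#' @param tree phylo tree.
#' @param tips tip labels spanning the clade.
#' @param include_stem include the branch subtending the clade (default
#'   `TRUE`).
#' @return Integer vector of child-node numbers identifying edges.
#' @export
clade_edges <- function(tree, tips, include_stem = TRUE) {
  bad <- setdiff(tips, tree$tip.label)
  if (length(bad)) stop("tip not in tree: ", bad[1])
  if (length(tips) == 1L) {
    node <- which(tree$tip.label == tips)
    return(node)
  }
  mrca <- ape::getMRCA(tree, tips)
  inside <- unlist(phangorn::Descendants(tree, mrca, "all"))
  tipidx <- which(tree$tip.label %in% tips)
  nodes <- sort(unique(c(inside, tipidx)))
  if (include_stem) nodes <- c(nodes, mrca)
  intersect(tree$edge[, 2L], nodes)
}

# ---- fitting ------------------------------------------------------------

#' Starting values for an alternative fit at the null's optimum
#'
#' `nested_start_m2a` maps an M1a optimum onto the M2a boundary (`p2`
#' essentially 0), and `nested_start_modelA` maps a model-A-null optimum
#' onto model A (`omega2` just above 1), so refitting the alternative from
#' the null's optimum can never lower the log-likelihood.
#'
#' @param null_params fitted parameter list of the null model.
#' @param eps boundary offset.
#' @return Named list of model A / M2a starting values.
#' @export
nested_start_m2a <- function(null_params, eps = 1e-6) {
  list(kappa = null_params$kappa, omega0 = null_params$omega0, omega2 = 2,
       p0 = null_params$p0 * (1 - eps),
       p1 = (1 - null_params$p0) * (1 - eps))
}

#' @rdname nested_start_m2a
#' @export
nested_start_modelA <- function(null_params, eps = 1e-3) {
  utils::modifyList(null_params, list(omega2 = 1 + eps))
}

codon_param_transform <- function(model) {
  softmax3 <- function(x, y) {
    e <- c(exp(x), exp(y), 1)
    e / sum(e)
  }
  switch(model,
    M0 = list(
      n = 2L,
      to_params = function(th) list(kappa = exp(th[1]), omega = exp(th[2])),
      from_params = function(p) c(log(p$kappa), log(p$omega))),
    M1a = list(
      n = 3L,
      to_params = function(th) list(kappa = exp(th[1]),
                                    omega0 = stats::plogis(th[2]),
                                    p0 = stats::plogis(th[3])),
      from_params = function(p) c(log(p$kappa), stats::qlogis(p$omega0),
                                  stats::qlogis(p$p0))),
    M2a = list(
      n = 5L,
      to_params = function(th) {
        pr <- softmax3(th[4], th[5])
        list(kappa = exp(th[1]), omega0 = stats::plogis(th[2]),
             omega2 = 1 + exp(th[3]), p0 = pr[1], p1 = pr[2])
      },
      from_params = function(p) c(log(p$kappa), stats::qlogis(p$omega0),
                                  log(p$omega2 - 1),
                                  log(p$p0 / (1 - p$p0 - p$p1)),
                                  log(p$p1 / (1 - p$p0 - p$p1)))),
    A = list(
      n = 5L,
      to_params = function(th) {
        pr <- softmax3(th[4], th[5])
        list(kappa = exp(th[1]), omega0 = stats::plogis(th[2]),
             omega2 = 1 + exp(th[3]), p0 = pr[1], p1 = pr[2])
      },
      from_params = function(p) c(log(p$kappa), stats::qlogis(p$omega0),
                                  log(p$omega2 - 1),
                                  log(p$p0 / (1 - p$p0 - p$p1)),
                                  log(p$p1 / (1 - p$p0 - p$p1)))),
    A_null = list(
      n = 4L,
      to_params = function(th) {
        pr <- softmax3(th[3], th[4])
        list(kappa = exp(th[1]), omega0 = stats::plogis(th[2]),
             omega2 = 1, p0 = pr[1], p1 = pr[2])
      },
      from_params = function(p) c(log(p$kappa), stats::qlogis(p$omega0),
                                  log(p$p0 / (1 - p$p0 - p$p1)),
                                  log(p$p1 / (1 - p$p0 - p$p1)))),
    stop("unknown model: ", model))
}

codon_default_start <- function(model) {
  switch(model,
    M0 = list(kappa = 2, omega = 0.5),
    M1a = list(kappa = 2, omega0 = 0.3, p0 = 0.6),
    M2a = list(kappa = 2, omega0 = 0.3, omega2 = 2.5, p0 = 0.5, p1 = 0.35),
    A = list(kappa = 2, omega0 = 0.3, omega2 = 2.5, p0 = 0.5, p1 = 0.35),
    A_null = list(kappa = 2, omega0 = 0.3, omega2 = 1, p0 = 0.5, p1 = 0.35))
}

#' Fit a codon model by maximum likelihood
#'
#' Multi-start quasi-Newton (BFGS) maximization on unconstrained transforms
#' of the parameters (log kappa, logit omega0, log(omega2 - 1), softmax
#' proportions). Branch lengths are taken from the input tree and held
#' fixed. The best start is returned; all starts are logged.
#'
#' @param tree phylo tree (tips matching alignment rows).
#' @param caln codon alignment.
#' @param model `"M0"`, `"M1a"`, `"M2a"`, `"A"` or `"A_null"`.
#' @param foreground_edges child-node edge ids for model A (see
#'   [clade_edges()]).
#' @param codon_freqs `"f3x4"` (default), `"equal"`, or a 61-vector.
#' @param n_starts number of optimizer starts (default 3).
#' @param seed seed for start jitter.
#' @param start optional named list of starting parameter values.
#' @param reltol relative convergence tolerance.
#' @return List of class `"radphy_codon_fit"`: `model`, `params`, `logLik`,
#'   `starts` (per-start log), `convergence`, plus the inputs needed by
#'   [eb_site_posteriors()].
#' @export
fit_codon_model <- function(tree, caln, model = c("M0", "M1a", "M2a", "A", "A_null"),
                            foreground_edges = NULL, codon_freqs = "f3x4",
                            n_starts = 3L, seed = 1L, start = NULL,
                            reltol = 1e-8) {
  model <- match.arg(model)
  if (model %in% c("A", "A_null") && !length(foreground_edges))
    stop("model A requires a non-empty foreground branch set")
  pi_ <- resolve_codon_freqs(codon_freqs, caln)
  idx <- caln_to_indices(caln)[tree$tip.label, , drop = FALSE]
  tf <- codon_param_transform(model)
  fg <- foreground_edges %||% integer(0)
  prep <- codon_prep(tree, idx)
  negll <- function(th) {
    th <- pmax(pmin(th, 30), -30)  # keep transforms in floating-point range
    v <- tryCatch({
      p <- tf$to_params(th)
      cls <- codon_class_site_logliks(tree, idx, model_site_classes(model, p),
                                      p$kappa, pi_, fg, prep = prep)
      -mixture_total_loglik(cls)
    }, error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  base <- tf$from_params(start %||% codon_default_start(model))
  default <- tf$from_params(codon_default_start(model))
  starts <- with_seed(derive_seed(seed, paste0("codonfit_", model)), {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1L) base
      else if (i == 2L && any(base != default)) default
      else default + stats::rnorm(tf$n, 0, 0.75)
    })
  })
  runs <- lapply(starts, function(th0) {
    tryCatch(stats::optim(th0, negll, method = "BFGS",
                          control = list(reltol = reltol, maxit = 500)),
             error = function(e) list(value = Inf, convergence = 1L,
                                      par = th0, message = conditionMessage(e)))
  })
  vals <- vapply(runs, `[[`, 0, "value")
  if (all(!is.finite(vals))) stop("codon model optimization failed in all starts")
  best <- runs[[which.min(vals)]]
  params <- tf$to_params(best$par)
  structure(list(model = model, params = params, logLik = -best$value,
                 convergence = best$convergence,
                 starts = data.frame(start = seq_along(runs),
                                     logLik = -vals,
                                     converged = vapply(runs, function(r)
                                       identical(r$convergence, 0L), TRUE)),
                 tree = tree, caln = caln, codon_freqs = pi_,
                 foreground_edges = fg),
            class = "radphy_codon_fit")
}

#' @export
print.radphy_codon_fit <- function(x, ...) {
  cat(sprintf("Codon model %s: logL = %.4f\n", x$model, x$logLik))
  str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Likelihood ratio test between nested codon fits
#'
#' Statistic `2 (logL_alt - logL_null)` clamped at zero. Degrees of freedom
#' default to the standard comparisons (M1a vs M2a: 2; model A vs its null:
#' 1). For the model A comparison a 50:50 mixture of a point mass at 0 and
#' chi-square(1) is available as the null distribution.
#'
#' @param null,alt fitted models from [fit_codon_model()].
#' @param df degrees of freedom; inferred for standard pairs when `NULL`.
#' @param mixture use the 50:50 mixture null (model A vs A_null).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(null, alt, df = NULL, mixture = FALSE) {
  pairs <- list(c("M0", "M1a"), c("M1a", "M2a"), c("M0", "M2a"),
                c("M1a", "A"), c("A_null", "A"))
  ok <- any(vapply(pairs, function(p)
    identical(p, c(null$model, alt$model)), TRUE))
  if (!ok) stop("models not nested: ", null$model, " vs ", alt$model)
  if (is.null(df)) {
    df <- switch(paste(null$model, alt$model),
                 "M1a M2a" = 2L, "A_null A" = 1L, "M0 M1a" = 1L,
                 "M0 M2a" = 3L, "M1a A" = 2L)
  }
  if (alt$logLik < null$logLik - 1e-4)
    warning("alternative logL below null logL; optimizer may not have converged")
  stat <- max(0, 2 * (alt$logLik - null$logLik))
  p <- if (mixture) {
    if (stat == 0) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p)
}

# ---- empirical Bayes site posteriors ------------------------------------

selected_class_ids <- function(model) {
  switch(model, M2a = 3L, A = c(3L, 4L),
         stop("site posteriors require an M2a or model A fit"))
}

#' Empirical Bayes posteriors for positively selected sites
#'
#' NEB plugs the MLEs into Bayes' rule per site. BEB averages the
#' posterior over a uniform grid (`grid_d` points per dimension) on the
#' class proportions and the omega parameters (`omega0` in (0,1), `omega2`
#' in (1,11)), with the remaining parameters fixed at their MLEs; grid
#' weights are the normalized data likelihoods. Sites whose positively
#' selected class posterior exceeds 0.95 (and 0.99) are flagged.
#'
#' @param fit M2a or model A fit from [fit_codon_model()].
#' @param method `"BEB"` (default) or `"NEB"`.
#' @param grid_d grid points per dimension for BEB (default 10).
#' @param site_numbers optional site labels (e.g. reference codon
#'   numbering); default 1..S alignment numbering.
#' @return data.frame of class `"radphy_site_posterior"` with columns
#'   `site`, per-class posteriors, `p_selected`, `selected_095`,
#'   `selected_099`, and the method in attribute `"method"`.
#' @export
eb_site_posteriors <- function(fit, method = c("BEB", "NEB"), grid_d = 10L,
                               site_numbers = NULL) {
  method <- match.arg(method)
  sel <- selected_class_ids(fit$model)
  tree <- fit$tree; pi_ <- fit$codon_freqs
  idx <- caln_to_indices(fit$caln)[tree$tip.label, , drop = FALSE]
  S <- ncol(idx)
  site_numbers <- site_numbers %||% seq_len(S)
  kappa <- fit$params$kappa
  if (method == "NEB") {
    cls <- codon_class_site_logliks(tree, idx,
                                    model_site_classes(fit$model, fit$params),
                                    kappa, pi_, fit$foreground_edges)
    w <- cls$props * exp(sweep(cls$ll, 2L, apply(cls$ll, 2L, max), "-"))
    post <- sweep(w, 2L, colSums(w), "/")
  } else {
    gridpts <- (2 * seq_len(grid_d) - 1) / (2 * grid_d)
    w0s <- gridpts
    w2s <- 1 + 10 * gridpts
    pp <- expand.grid(p0 = gridpts, p1 = gridpts)
    pp <- pp[pp$p0 + pp$p1 < 1, , drop = FALSE]
    nclass <- if (fit$model == "M2a") 3L else 4L
    post_acc <- matrix(0, nclass, S)
    logm <- c(); combos <- list()
    # branch-length scaling fixed at the MLE, as the grid varies only the
    # site-class parameters, not the tree
    parts <- codon_rate_parts(kappa, pi_)
    mle_classes <- model_site_classes(fit$model, fit$params)
    mle_scale <- sum(vapply(mle_classes, function(cl)
      cl$prop * (parts["syn"] + cl$bg * parts["nonsyn"]), 0))
    prep <- codon_prep(tree, idx)
    for (w0 in w0s) for (w2 in w2s) {
      p_tmp <- utils::modifyList(fit$params, list(omega0 = w0, omega2 = w2))
      # class site logliks depend on (w0, w2) only; proportions mix later
      cls <- codon_class_site_logliks(
        tree, idx, model_site_classes(fit$model,
                                      utils::modifyList(p_tmp, list(p0 = 0.4, p1 = 0.4))),
        kappa, pi_, fit$foreground_edges, scale_rate = mle_scale, prep = prep)
      for (r in seq_len(nrow(pp))) {
        p0 <- pp$p0[r]; p1 <- pp$p1[r]; p2 <- 1 - p0 - p1
        props <- if (fit$model == "M2a") c(p0, p1, p2)
                 else c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
        mx <- apply(cls$ll, 2L, max)
        wmat <- props * exp(sweep(cls$ll, 2L, mx, "-"))
        sitemix <- colSums(wmat)
        combos[[length(combos) + 1L]] <- sweep(wmat, 2L, sitemix, "/")
        logm <- c(logm, sum(log(sitemix) + mx))
      }
    }
    wts <- exp(logm - max(logm))
    wts <- wts / sum(wts)
    for (i in seq_along(combos)) post_acc <- post_acc + wts[i] * combos[[i]]
    post <- post_acc
  }
  p_sel <- colSums(post[sel, , drop = FALSE])
  out <- data.frame(site = site_numbers, t(post))
  names(out)[-1] <- paste0("class", seq_len(nrow(post)))
  out$p_selected <- p_sel
  out$selected_095 <- p_sel > 0.95
  out$selected_099 <- p_sel > 0.99
  attr(out, "method") <- method
  class(out) <- c("radphy_site_posterior", class(out))
  out
}
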