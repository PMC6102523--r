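# Goldman-Yang (1994) codon substitution machinery: rate matrix
# construction, transition probabilities through spectral
# decomposition of the reversible generator, Felsenstein pruning over
# a fixed tree, and sequence simulation (shared with the synthetic
# data generator).

#' @noRd
codon_pair_features <- function() {
  if (!is.null(.codon_cache$feat)) return(.codon_cache$feat)
  sc <- sense_codons()
  n <- length(sc)
  aa <- sense_aa()
  chars <- do.call(rbind, strsplit(sc, ""))
  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(chars[, p], chars[, p], "!=")
  pos <- matrix(0L, n, n)
  for (p in 1:3) pos[outer(chars[, p], chars[, p], "!=") & ndiff == 1L] <- p
  single <- ndiff == 1L
  ts <- matrix(FALSE, n, n)
  idx <- which(single, arr.ind = TRUE)
  b1 <- chars[cbind(idx[, 1], pos[single])]
  b2 <- chars[cbind(idx[, 2], pos[single])]
  ts[single] <- is_transition(b1, b2)
  syn <- outer(aa, aa, "==")
  idx <- which(single)
  .codon_cache$feat <- list(
    single = single, transition = ts, synonymous = syn,
    idx = idx,                       # linear indices of single-change pairs
    idx_ts = ts[idx],                # transition flag per index
    idx_syn = syn[idx],              # synonymous flag per index
    idx_col = ((idx - 1L) %/% n) + 1L)  # target codon (column) per index
  .codon_cache$feat
}

#' Build a scaled GY94 codon rate matrix
#'
#' Off-diagonal entries are nonzero only for single-base changes and
#' equal \eqn{\pi_j} times 1, \eqn{\kappa}, \eqn{\omega} or
#' \eqn{\omega\kappa} for synonymous transversions/transitions and
#' nonsynonymous transversions/transitions respectively. The matrix
#' is scaled so the expected substitution flux
#' \eqn{\sum_i \pi_i \sum_{j \ne i} q_{ij}} equals one per codon per
#' unit branch length.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Equilibrium frequencies over the 61 sense codons
#'   (default uniform).
#' @return 61 x 61 generator matrix with codon dimnames.
#' @export
build_rate_matrix <- function(kappa, omega, pi = NULL) {
  sc <- sense_codons()
  n <- length(sc)
  if (is.null(pi)) pi <- rep(1 / n, n)
  stopifnot(length(pi) == n, all(pi > 0), abs(sum(pi) - 1) < 1e-8,
            kappa > 0, omega >= 0)
  f <- codon_pair_features()
  v <- ifelse(f$idx_ts, kappa, 1) * ifelse(f$idx_syn, 1, omega) *
       pi[f$idx_col]                 # q_ij = rate_ij * pi_j
  Q <- matrix(0, n, n, dimnames = list(sc, sc))
  Q[f$idx] <- v
  diag(Q) <- -rowSums(Q)
  flux <- -sum(pi * diag(Q))
  if (flux > 0) Q <- Q / flux
  attr(Q, "pi") <- pi
  Q
}

# Spectral decomposition of a reversible generator.
# With D = diag(sqrt(pi)), S = D Q D^-1 is symmetric; P(t) =
# D^-1 V exp(Lambda t) V' D.
#' @noRd
codon_eig <- function(Q) {
  pi <- attr(Q, "pi")
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / d, B = t(e$vectors) * rep(d, each = length(d)),
       values = e$values, pi = pi)
}

# Memoised decomposition: model fitting re-evaluates the same
# (kappa, omega, pi) triples many times during finite-difference
# gradients, so decompositions are cached (and the cache bounded).
#' @noRd
codon_eig_cached <- function(kappa, omega, pi = NULL) {
  if (is.null(.codon_cache$eig)) .codon_cache$eig <- new.env(parent = emptyenv())
  key <- paste(format(kappa, digits = 15), format(omega, digits = 15),
               if (is.null(pi)) "u" else
                 format(sum(pi * seq_along(pi)) + pi[1L] + pi[31L], digits = 15),
               sep = "|")
  hit <- .codon_cache$eig[[key]]
  if (!is.null(hit)) return(hit)
  if (length(ls(.codon_cache$eig)) > 400L)
    .codon_cache$eig <- new.env(parent = emptyenv())
  val <- codon_eig(build_rate_matrix(kappa, omega, pi))
  assign(key, val, envir = .codon_cache$eig)
  val
}

#' @noRd
codon_pmat <- function(eig, t) {
  P <- eig$A %*% (exp(eig$values * t) * eig$B)
  P[P < 0] <- 0
  P
}

#' Encode a codon alignment as an integer matrix
#'
#' Rows are sequences, columns codon sites; entries index the 61 sense
#' codons, with NA for gaps, ambiguous codons or in-frame stops
#' (treated as missing data in the likelihood).
#' @param caln \code{codon_alignment} (or named codon strings).
#' @return Integer matrix with sequence ids as rownames.
#' @export
encode_codon_alignment <- function(caln) {
  sc <- sense_codons()
  rows <- lapply(unclass(caln), function(r) match(split_codons(r), sc))
  m <- do.call(rbind, rows)
  rownames(m) <- names(caln)
  m
}

# Felsenstein pruning. `class_eigs` is a list of eigendecompositions
# (one per site class); `fg_class_eigs`, when given, replaces the
# class generator on the edges listed in `fg_edges` (branch-site
# models). Returns per-class per-site log-likelihood matrix.
#' @noRd
prune_site_loglik <- function(tree, X, class_eigs, fg_class_eigs = NULL,
                              fg_edges = integer()) {
  # edge indices refer to the tree as passed in; identify foreground
  # edges by their child node, which is stable under reordering
  fg_children <- if (length(fg_edges)) tree$edge[fg_edges, 2L] else integer()
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nsite <- ncol(X)
  nstate <- 61L
  X <- X[tree$tip.label, , drop = FALSE]
  nclass <- length(class_eigs)
  out <- matrix(NA_real_, nclass, nsite)
  tip_partial <- function(k) {
    L <- matrix(0, nstate, nsite)
    obs <- X[k, ]
    L[cbind(obs[!is.na(obs)], which(!is.na(obs)))] <- 1
    L[, is.na(obs)] <- 1
    L
  }
  for (cls in seq_len(nclass)) {
    partial <- vector("list", ntip + nnode)
    logscale <- numeric(nsite)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      eg <- if (child %in% fg_children && !is.null(fg_class_eigs))
        fg_class_eigs[[cls]] else class_eigs[[cls]]
      P <- codon_pmat(eg, tree$edge.length[e])
      Lc <- if (child <= ntip) tip_partial(child) else partial[[child]]
      contrib <- P %*% Lc
      if (is.null(partial[[par]])) partial[[par]] <- contrib
      else partial[[par]] <- partial[[par]] * contrib
      sc <- .colSums(partial[[par]], nstate, nsite)
      sc[sc <= 0] <- 1
      partial[[par]] <- partial[[par]] / rep(sc, each = nstate)
      logscale <- logscale + log(sc)
    }
    root <- tree$edge[nrow(tree$edge), 1L]
    lik <- as.numeric(class_eigs[[cls]]$pi %*% partial[[root]])
    out[cls, ] <- log(lik) + logscale
  }
  out
}

#' Log-likelihood of a codon alignment under a (mixture) GY94 model
#'
#' Felsenstein pruning per site and site class; the site likelihood of
#' a mixture model is the weighted average over classes. Gap and
#' ambiguous codons contribute all-ones partial likelihoods.
#'
#' @param tree \code{phylo} with branch lengths; tip labels must match
#'   alignment ids.
#' @param caln \code{codon_alignment} or pre-encoded integer matrix.
#' @param omegas Numeric vector of class omega values.
#' @param weights Class probabilities (same length, summing to one).
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default uniform).
#' @param fg_omegas,fg_edges Optional foreground class omegas and edge
#'   indices for branch-site models.
#' @return List: \code{lnL}, \code{site_loglik} (class x site matrix),
#'   \code{weights}.
#' @export
codon_loglik <- function(tree, caln, omegas, weights = rep(1 / length(omegas), length(omegas)),
                         kappa = 2, pi = NULL, fg_omegas = NULL, fg_edges = integer()) {
  stopifnot(abs(sum(weights) - 1) < 1e-6, length(omegas) == length(weights))
  X <- if (is.matrix(caln)) caln else encode_codon_alignment(caln)
  if (!setequal(rownames(X), tree$tip.label))
    stop("tree tips and alignment ids differ")
  class_eigs <- lapply(omegas, function(w) codon_eig_cached(kappa, w, pi))
  fg_eigs <- if (!is.null(fg_omegas))
    lapply(fg_omegas, function(w) codon_eig_cached(kappa, w, pi))
  sl <- prune_site_loglik(tree, X, class_eigs, fg_eigs, fg_edges)
  # log sum exp over classes with weights
  mx <- apply(sl, 2L, max)
  site_mix <- mx + log(colSums(exp(sweep(sl, 2L, mx)) * weights))
  list(lnL = sum(site_mix), site_loglik = sl, weights = weights,
       site_mix_loglik = site_mix)
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies are multiplied across the
#' three codon positions and renormalized over the 61 sense codons. A
#' small pseudo-frequency keeps unobserved states strictly positive.
#'
#' @param caln \code{codon_alignment}.
#' @return Numeric vector of 61 codon frequencies.
#' @export
f3x4_freqs <- function(caln) {
  rows <- unclass(caln)
  cod <- unlist(lapply(rows, split_codons), use.names = FALSE)
  cod <- cod[!grepl("[-N]", cod)]
  freq <- matrix(0, 3, 4, dimnames = list(NULL, BASES))
  for (p in 1:3) {
    tb <- table(factor(substr(cod, p, p), levels = BASES))
    freq[p, ] <- (tb + 0.5) / sum(tb + 0.5)
  }
  sc <- sense_codons()
  pi <- freq[1L, substr(sc, 1, 1)] * freq[2L, substr(sc, 2, 2)] *
        freq[3L, substr(sc, 3, 3)]
  pi / sum(pi)
}

#' Simulate codon sequences along a tree
#'
#' Sites are assigned to omega classes with the given weights; the
#' root sequence is drawn from the equilibrium frequencies and evolved
#' along each branch with the corresponding transition matrices.
#' Foreground omegas, when given, replace the class omega on the
#' listed edges (branch-site simulation).
#'
#' @param tree \code{phylo} with branch lengths.
#' @param nsites Number of codon sites.
#' @param omegas,weights Site-class omegas and probabilities.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default uniform).
#' @param fg_omegas,fg_edges Optional branch-site foreground setup.
#' @param seed Integer seed.
#' @return List: \code{caln} (\code{codon_alignment}),
#'   \code{site_class} (integer vector of true classes).
#' @export
simulate_codon_alignment <- function(tree, nsites, omegas, weights = rep(1 / length(omegas), length(omegas)),
                                     kappa = 2, pi = NULL, fg_omegas = NULL,
                                     fg_edges = integer(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- sense_codons()
  n <- length(sc)
  if (is.null(pi)) pi <- rep(1 / n, n)
  site_class <- sample.int(length(omegas), nsites, replace = TRUE, prob = weights)
  eigs <- lapply(omegas, function(w) codon_eig(build_rate_matrix(kappa, w, pi)))
  fg_eigs <- if (!is.null(fg_omegas))
    lapply(fg_omegas, function(w) codon_eig(build_rate_matrix(kappa, w, pi)))
  fg_children <- if (length(fg_edges)) tree$edge[fg_edges, 2L] else integer()
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1L]
  states <- matrix(NA_integer_, ntip + tree$Nnode, nsites)
  states[root, ] <- sample.int(n, nsites, replace = TRUE, prob = pi)
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    for (cls in unique(site_class)) {
      eg <- if (child %in% fg_children && !is.null(fg_eigs)) fg_eigs[[cls]] else eigs[[cls]]
      P <- codon_pmat(eg, tree$edge.length[e])
      sites <- which(site_class == cls)
      ps <- states[par, sites]
      for (s in unique(ps)) {
        w <- sites[ps == s]
        states[child, w] <- sample.int(n, length(w), replace = TRUE, prob = P[s, ])
      }
    }
  }
  rows <- vapply(seq_len(ntip), function(k)
    paste0(sc[states[k, ]], collapse = ""), character(1))
  names(rows) <- tree$tip.label
  list(caln = structure(rows, n_codon_columns = nsites, class = "codon_alignment"),
       site_class = site_class)
}

#' Edges of the clade spanned by a set of tips
#'
#' Returns the indices of all edges inside the clade defined by the
#' most recent common ancestor of \code{tips}, including the stem
#' edge; used to mark foreground branches.
#'
#' @param tree \code{phylo}.
#' @param tips Character vector of tip labels.
#' @return Integer vector of edge indices.
#' @export
clade_edges <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  tipno <- match(tips, tree$tip.label)
  if (length(tipno) == 1L) {
    node <- tipno
  } else {
    node <- ape::getMRCA(tree, tipno)
  }
  desc <- c(node, phangorn::Descendants(tree, node, type = "all"))
  which(tree$edge[, 2L] %in% desc)
}
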