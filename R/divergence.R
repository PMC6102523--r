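# Gu-style type-I and type-II functional divergence between two
# subfamily clusters.
#
# Type I: a two-state mixture over sites. With probability theta the
# site's evolutionary rates are independent between the clusters
# (functional divergence); with probability 1 - theta the clusters
# share a single gamma-distributed rate. Per-cluster substitution
# counts come from Fitch parsimony, are Poisson given the rate, and
# integrate to (bivariate) negative binomial likelihoods. Parameters
# (theta, gamma shape, per-cluster tree depths) are estimated by
# maximum likelihood; Qk is the posterior of the divergence state.
#
# Type II: a moment estimator on the cluster consensus sequences
# (radical property shifts among sites conserved in both clusters,
# in excess of the background expectation). It is not clamped, so
# small or negative estimates are reported as computed.

#' Default amino-acid property partition
#'
#' Five biochemical classes: positively charged (KRH), negatively
#' charged (DE), polar (STNQY), hydrophobic (AVLIMFW) and special
#' (CGP). A substitution crossing classes is "radical".
#' @return Named character vector residue -> class.
#' @export
aa_property_partition <- function() {
  c(K = "pos", R = "pos", H = "pos",
    D = "neg", E = "neg",
    S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
    A = "hydro", V = "hydro", L = "hydro", I = "hydro", M = "hydro",
    F = "hydro", W = "hydro",
    C = "special", G = "special", P = "special")
}

#' Minimum substitution counts per alignment column (Fitch parsimony)
#'
#' @param aln \code{aa_alignment} restricted to one cluster.
#' @param tree \code{phylo} whose tips are the cluster members.
#' @return Integer vector of per-column minimum change counts; columns
#'   that are all-gap in the cluster are NA.
#' @export
site_substitution_counts <- function(aln, tree) {
  m <- aln_matrix(aln)
  stopifnot(setequal(rownames(m), tree$tip.label))
  m <- m[tree$tip.label, , drop = FALSE]
  nsite <- ncol(m)
  states <- AA20
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  tipset <- function(k) {
    s <- matrix(FALSE, length(states), nsite)
    res <- m[k, ]
    known <- res %in% states
    s[cbind(match(res[known], states), which(known))] <- TRUE
    s[, !known] <- TRUE  # gap or X: uninformative
    s
  }
  counts <- integer(nsite)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    cs <- if (child <= ntip) tipset(child) else sets[[child]]
    if (is.null(sets[[par]])) {
      sets[[par]] <- cs
    } else {
      inter <- sets[[par]] & cs
      empty <- colSums(inter) == 0L
      if (any(empty)) {
        uni <- sets[[par]] | cs
        inter[, empty] <- uni[, empty]
        counts[empty] <- counts[empty] + 1L
      }
      sets[[par]] <- inter
    }
  }
  allgap <- colSums(m != "-" & m != "X" & m != ".") == 0L
  counts[allgap] <- NA_integer_
  counts
}

#' @noRd
.theta1_loglik <- function(xA, xB, theta, alpha, dA, dB) {
  # independent state: product of NB marginals; shared state:
  # bivariate NB through the common gamma rate
  l_ind <- stats::dnbinom(xA, size = alpha, mu = dA, log = TRUE) +
           stats::dnbinom(xB, size = alpha, mu = dB, log = TRUE)
  p0 <- alpha / (alpha + dA + dB)
  l_sh <- lgamma(alpha + xA + xB) - lgamma(alpha) -
          lfactorial(xA) - lfactorial(xB) +
          alpha * log(p0) + xA * log(dA / (alpha + dA + dB)) +
          xB * log(dB / (alpha + dA + dB))
  mx <- pmax(l_ind, l_sh)
  site <- mx + log(theta * exp(l_ind - mx) + (1 - theta) * exp(l_sh - mx))
  list(lnL = sum(site), q = theta * exp(l_ind - site))
}

#' Estimate type-I functional divergence from paired site counts
#'
#' @param counts_a,counts_b Per-site substitution counts for the two
#'   clusters (same sites; NA sites dropped pairwise).
#' @return Object of class \code{divergence_estimate}: \code{theta},
#'   \code{se}, \code{lrt} (statistic for theta = 0), \code{p_value},
#'   \code{alpha} (gamma shape), \code{qk} (per-site posterior of the
#'   divergence state, NA where input was NA).
#' @export
estimate_theta1 <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b))
  keep <- !is.na(counts_a) & !is.na(counts_b)
  xA <- counts_a[keep]; xB <- counts_b[keep]
  if (!length(xA)) stop("no usable sites")
  if (all(xA == 0L) && all(xB == 0L))
    stop("all sites invariant in both clusters: theta undefined")
  negll <- function(par) {
    theta <- stats::plogis(par[1])
    alpha <- exp(par[2]); dA <- exp(par[3]); dB <- exp(par[4])
    if (!is.finite(alpha) || alpha > 1e4) return(1e10)
    r <- .theta1_loglik(xA, xB, theta, alpha, max(dA, 1e-8), max(dB, 1e-8))
    if (!is.finite(r$lnL)) return(1e10)
    -r$lnL
  }
  start <- c(stats::qlogis(0.3), log(1),
             log(max(mean(xA), 0.05)), log(max(mean(xB), 0.05)))
  fit <- stats::nlminb(start, negll, control = list(iter.max = 500L))
  theta <- stats::plogis(fit$par[1])
  alpha <- exp(fit$par[2]); dA <- exp(fit$par[3]); dB <- exp(fit$par[4])
  # SE by delta method on the logit scale
  h <- try(stats::optimHess(fit$par, negll), silent = TRUE)
  se <- NA_real_
  if (!inherits(h, "try-error")) {
    v <- try(solve(h), silent = TRUE)
    if (!inherits(v, "try-error") && v[1, 1] > 0)
      se <- sqrt(v[1, 1]) * theta * (1 - theta)  # d/dx plogis = p(1-p)
  }
  # LRT against theta = 0
  negll0 <- function(par) {
    alpha <- exp(par[1]); dA <- exp(par[2]); dB <- exp(par[3])
    r <- .theta1_loglik(xA, xB, 0, alpha, max(dA, 1e-8), max(dB, 1e-8))
    if (!is.finite(r$lnL)) return(1e10)
    -r$lnL
  }
  fit0 <- stats::nlminb(start[-1], negll0, control = list(iter.max = 500L))
  stat <- 2 * (fit0$objective - fit$objective)
  qk_all <- rep(NA_real_, length(counts_a))
  qk_all[keep] <- .theta1_loglik(xA, xB, theta, alpha, dA, dB)$q
  structure(list(type = "I", theta = theta, se = se,
                 lrt = stat,
                 p_value = stats::pchisq(max(stat, 0), 1L, lower.tail = FALSE),
                 alpha = alpha, depth_a = dA, depth_b = dB,
                 qk = qk_all, n_sites = length(xA)),
            class = "divergence_estimate")
}

#' @noRd
.cluster_consensus <- function(m, cutoff) {
  # per column: majority residue and whether its frequency among
  # non-gap residues reaches the conservation cutoff
  apply(m, 2L, function(col) {
    col <- col[col %in% AA20]
    if (!length(col)) return(c(NA_character_, NA))
    tb <- sort(table(col), decreasing = TRUE)
    cons <- names(tb)[1L]
    c(cons, as.character(tb[1L] / length(col) >= cutoff))
  })
}

#' Estimate type-II functional divergence from cluster consensus patterns
#'
#' Among sites conserved within both clusters, the fraction whose
#' consensus residues differ radically (cross the property partition)
#' is compared with its background expectation; the excess, rescaled
#' by the maximum possible excess, is the moment estimate of
#' theta-II. The background radical probability is computed from the
#' residue frequencies of the consensus sequences. The estimate is
#' reported as computed (it may be negative); the standard error
#' comes from a nonparametric bootstrap over columns.
#'
#' @param aln_a,aln_b \code{aa_alignment}s of the two clusters (same
#'   column space).
#' @param partition Residue -> property class map (default
#'   \code{\link{aa_property_partition}}).
#' @param conserved_cutoff Minimum within-cluster majority frequency
#'   for a site to count as conserved (default 0.9).
#' @param n_boot Bootstrap replicates for the SE.
#' @param seed Seed for the bootstrap.
#' @return \code{divergence_estimate} with \code{theta}, \code{se},
#'   \code{qk} (posterior of the radical-shift state per column) and
#'   bookkeeping counts.
#' @export
estimate_theta2 <- function(aln_a, aln_b, partition = aa_property_partition(),
                            conserved_cutoff = 0.9, n_boot = 200L, seed = 1L) {
  mA <- aln_matrix(aln_a); mB <- aln_matrix(aln_b)
  if (ncol(mA) != ncol(mB)) stop("cluster alignments differ in width")
  cA <- .cluster_consensus(mA, conserved_cutoff)
  cB <- .cluster_consensus(mB, conserved_cutoff)
  consA <- cA[1L, ]; consB <- cB[1L, ]
  okA <- cA[2L, ] == "TRUE"; okB <- cB[2L, ] == "TRUE"
  both <- which(okA & okB & !is.na(consA) & !is.na(consB))
  if (!length(both)) {
    warning("no sites conserved in both clusters: theta-II undefined")
    return(structure(list(type = "II", theta = NA_real_, se = NA_real_,
                          qk = rep(NA_real_, ncol(mA)), n_conserved = 0L),
                     class = "divergence_estimate"))
  }
  stat_fun <- function(cols) {
    ca <- consA[cols]; cb <- consB[cols]
    diffs <- ca != cb
    radical <- diffs & partition[ca] != partition[cb]
    freqs <- table(factor(c(ca, cb), levels = names(partition)))
    f <- as.numeric(freqs) / sum(freqs)
    cls <- partition[names(partition)]
    # background P(radical | residues differ)
    pdiff <- 1 - sum(f^2)
    prad <- 0
    for (cl in unique(cls)) {
      fc <- sum(f[cls == cl])
      prad <- prad + fc * (1 - fc)
    }
    a_r <- if (pdiff > 0) prad / pdiff else 0
    d_obs <- mean(diffs)
    exp_rad <- a_r * d_obs
    obs_rad <- mean(radical)
    theta <- (obs_rad - exp_rad) / (1 - exp_rad)
    list(theta = theta, a_r = a_r, d_obs = d_obs,
         radical = radical, diffs = diffs)
  }
  est <- stat_fun(both)
  set.seed(seed)
  boots <- replicate(n_boot, {
    cols <- sample(both, length(both), replace = TRUE)
    stat_fun(cols)$theta
  })
  se <- stats::sd(boots, na.rm = TRUE)
  # Qk: posterior that a conserved-in-both column is a radical-shift
  # (type II) site, under the two-state mixture implied by theta
  theta_q <- min(max(est$theta, 0), 1 - 1e-12)
  p_null_rad <- est$a_r * est$d_obs
  qk <- rep(NA_real_, ncol(mA))
  q_rad <- if (theta_q > 0)
    theta_q / (theta_q + (1 - theta_q) * p_null_rad) else 0
  qk[both] <- ifelse(est$radical, q_rad, 0)
  structure(list(type = "II", theta = est$theta, se = se, qk = qk,
                 n_conserved = length(both),
                 n_radical = sum(est$radical),
                 background_radical_rate = est$a_r),
            class = "divergence_estimate")
}

#' Type-I and type-II divergence between two clusters of one family
#'
#' Convenience wrapper: extracts the cluster subtrees and alignment
#' rows, runs Fitch counting and both estimators, and reports sites
#' with Qk above the calling threshold.
#'
#' @param aln Family \code{aa_alignment}.
#' @param tree Family \code{phylo} containing all cluster members.
#' @param cluster_a,cluster_b Character vectors of member ids
#'   (disjoint, >= 4 each).
#' @param qk_threshold Reporting threshold on the posterior
#'   (default 0.95).
#' @param ref_id Optional reference row for site numbering.
#' @return List with \code{theta1}, \code{theta2}, \code{sites_type1},
#'   \code{sites_type2} (data.frames of called sites).
#' @export
functional_divergence <- function(aln, tree, cluster_a, cluster_b,
                                  qk_threshold = 0.95, ref_id = NULL) {
  stopifnot(length(intersect(cluster_a, cluster_b)) == 0L)
  if (length(cluster_a) < 4L || length(cluster_b) < 4L)
    stop("each cluster needs >= 4 sequences")
  sub <- function(ids) {
    tr <- ape::keep.tip(tree, ids)
    al <- as_aa_alignment(unclass(aln)[ids])
    list(tree = tr, aln = al)
  }
  A <- sub(cluster_a); B <- sub(cluster_b)
  xa <- site_substitution_counts(A$aln, A$tree)
  xb <- site_substitution_counts(B$aln, B$tree)
  t1 <- estimate_theta1(xa, xb)
  t2 <- estimate_theta2(A$aln, B$aln)
  site_table <- function(qk) {
    called <- which(!is.na(qk) & qk > qk_threshold)
    refm <- if (!is.null(ref_id)) {
      codons <- strsplit(unclass(aln)[[match(ref_id, names(aln))]], "")[[1]]
      ungapped <- cumsum(codons != "-")
      data.frame(ref_site = ifelse(codons[called] == "-", NA, ungapped[called]),
                 ref_aa = codons[called])
    } else data.frame(ref_site = rep(NA_integer_, length(called)),
                      ref_aa = rep(NA_character_, length(called)))
    cbind(data.frame(site = called, qk = qk[called]), refm)
  }
  list(theta1 = t1, theta2 = t2,
       sites_type1 = site_table(t1$qk),
       sites_type2 = site_table(t2$qk))
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat("Type", x$type, "functional divergence: theta =",
      formatC(x$theta, digits = 3, format = "f"),
      "+/-", formatC(x$se, digits = 3, format = "f"), "\n")
  if (!is.null(x$lrt)) cat("LRT =", formatC(x$lrt, digits = 3, format = "f"),
                           " p =", format.pval(x$p_value), "\n")
  invisible(x)
}
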