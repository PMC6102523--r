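# Fitting GY94 site and branch-site models by maximum likelihood,
# likelihood-ratio tests, and empirical-Bayes identification of
# positively selected sites (NEB and a grid Bayes empirical Bayes for
# M8).

#' Discretized beta categories (equal probability, category means)
#'
#' @param p,q Beta shape parameters.
#' @param K Number of categories.
#' @return Numeric vector of K category mean omegas in (0, 1).
#' @export
beta_class_omegas <- function(p, q, K = 10L) {
  br <- stats::qbeta(seq(0, 1, length.out = K + 1L), p, q)
  m <- K * (p / (p + q)) *
    (stats::pbeta(br[-1L], p + 1, q) - stats::pbeta(br[-(K + 1L)], p + 1, q))
  pmin(pmax(m, 1e-8), 1 - 1e-8)
}

#' @noRd
.softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

#' @noRd
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# model -> list(start, unpack) where unpack(par) returns
# list(kappa, omegas, weights, np_omega)
#' @noRd
.site_model_map <- function(model, K) {
  switch(model,
    M0 = list(
      start = c(log(2), log(0.3)),
      unpack = function(par) list(
        kappa = .clamp(exp(par[1]), 0.01, 100),
        omegas = .clamp(exp(par[2]), 1e-6, 50),
        weights = 1, np_omega = 1L)),
    M3 = list(
      start = c(log(2), 0, 0, log(0.05), log(0.3), log(1.2)),
      unpack = function(par) list(
        kappa = .clamp(exp(par[1]), 0.01, 100),
        omegas = .clamp(exp(par[4:6]), 1e-6, 50),
        weights = .softmax(c(par[2], par[3], 0)),
        np_omega = 5L)),
    M7 = list(
      start = c(log(2), log(0.8), log(2)),
      unpack = function(par) {
        p <- .clamp(exp(par[2]), 0.005, 99)
        q <- .clamp(exp(par[3]), 0.005, 99)
        list(kappa = .clamp(exp(par[1]), 0.01, 100),
             omegas = beta_class_omegas(p, q, K),
             weights = rep(1 / K, K), np_omega = 2L,
             extra = c(p = p, q = q))
      }),
    M8 = list(
      start = c(log(2), stats::qlogis(0.9), log(0.8), log(2), log(0.5)),
      unpack = function(par) {
        p0 <- .clamp(stats::plogis(par[2]), 1e-6, 1 - 1e-6)
        p <- .clamp(exp(par[3]), 0.005, 99)
        q <- .clamp(exp(par[4]), 0.005, 99)
        ws <- 1 + .clamp(exp(par[5]), 1e-8, 49)
        list(kappa = .clamp(exp(par[1]), 0.01, 100),
             omegas = c(beta_class_omegas(p, q, K), ws),
             weights = c(rep(p0 / K, K), 1 - p0), np_omega = 4L,
             extra = c(p0 = p0, p = p, q = q, omega_s = ws))
      }),
    stop("unknown site model: ", model))
}

#' Fit a GY94 site model
#'
#' Fits M0 (one ratio), M3 (discrete, 3 classes), M7 (beta, K
#' categories) or M8 (beta plus one omega >= 1 class). Under M0 the
#' branch lengths are optimized jointly with the model; for the other
#' models they are held fixed (at the values of the supplied tree,
#' conventionally the M0 estimates) so that nested models share one
#' branch-length set. Multiple random restarts guard against local
#' optima; the best likelihood is kept.
#'
#' @param model One of \code{"M0"}, \code{"M3"}, \code{"M7"}, \code{"M8"}.
#' @param tree \code{phylo} with branch lengths (used as starting
#'   values under M0, fixed otherwise).
#' @param caln \code{codon_alignment}.
#' @param freqs \code{"F3x4"} (default) or \code{"uniform"} codon
#'   frequencies.
#' @param K Discretization categories for the beta models.
#' @param n_restarts Random restarts (default 3).
#' @param seed Seed for the restart jitter.
#' @param fix_kappa Optional fixed transition/transversion ratio.
#'   Like the branch lengths, kappa is conventionally estimated once
#'   under M0 and reused by the mixture models
#'   (\code{\link{fit_site_models}} does this); leave \code{NULL} to
#'   estimate it within this fit.
#' @return Object of class \code{site_model_fit}: model name,
#'   \code{lnL}, \code{kappa}, \code{omegas}, \code{weights},
#'   \code{params}, \code{np_omega}, \code{tree} (with the branch
#'   lengths used), \code{site_loglik}, \code{pi}, \code{caln},
#'   \code{convergence}.
#' @export
fit_site_model <- function(model = c("M0", "M3", "M7", "M8"), tree, caln,
                           freqs = c("F3x4", "uniform"), K = 10L,
                           n_restarts = 3L, seed = 1L, fix_kappa = NULL) {
  model <- match.arg(model)
  freqs <- match.arg(freqs)
  X <- encode_codon_alignment(caln)
  pi <- if (freqs == "F3x4") f3x4_freqs(caln) else NULL
  map <- .site_model_map(model, K)
  if (!is.null(fix_kappa)) {
    stopifnot(model != "M0", fix_kappa > 0)
    inner <- map
    map <- list(start = inner$start[-1L],
                unpack = function(par) inner$unpack(c(log(fix_kappa), par)))
  }
  optimize_bl <- model == "M0"
  nedge <- nrow(tree$edge)
  el0 <- tree$edge.length
  if (is.null(el0) || any(!is.finite(el0))) el0 <- rep(0.1, nedge)
  el0 <- pmax(el0, 1e-4)

  objective <- function(par) {
    mp <- map$unpack(par[seq_along(map$start)])
    tr <- tree
    if (optimize_bl)
      tr$edge.length <- .clamp(exp(par[-seq_along(map$start)]), 1e-8, 50)
    ll <- try(codon_loglik(tr, X, mp$omegas, mp$weights, mp$kappa, pi)$lnL,
              silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }

  base_start <- map$start
  if (optimize_bl) base_start <- c(base_start, log(el0))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    start <- if (r == 1L) base_start else base_start + stats::rnorm(length(base_start), 0, 0.4)
    fit <- try(stats::nlminb(start, objective,
                             control = list(iter.max = 500L, eval.max = 2000L,
                                            rel.tol = 1e-7)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("optimization failed for model ", model)
  mp <- map$unpack(best$par[seq_along(map$start)])
  tr <- tree
  if (optimize_bl)
    tr$edge.length <- .clamp(exp(best$par[-seq_along(map$start)]), 1e-8, 50)
  ll <- codon_loglik(tr, X, mp$omegas, mp$weights, mp$kappa, pi)
  structure(list(
    model = model, lnL = -best$objective, kappa = mp$kappa,
    omegas = mp$omegas, weights = mp$weights,
    params = if (!is.null(mp$extra)) mp$extra else c(omega = mp$omegas[1]),
    np_omega = mp$np_omega, tree = tr, pi = pi,
    site_loglik = ll$site_loglik, site_mix_loglik = ll$site_mix_loglik,
    caln = caln, K = K,
    convergence = best$convergence == 0), class = "site_model_fit")
}

#' Fit all four site models with shared M0 branch lengths
#'
#' @inheritParams fit_site_model
#' @param models Models to fit (default all four).
#' @return Named list of \code{site_model_fit} objects plus
#'   \code{lrt_m0_m3} and \code{lrt_m7_m8} results.
#' @export
fit_site_models <- function(tree, caln, models = c("M0", "M3", "M7", "M8"),
                            freqs = "F3x4", K = 10L, n_restarts = 3L, seed = 1L) {
  fits <- list()
  fits$M0 <- fit_site_model("M0", tree, caln, freqs, K, n_restarts, seed)
  tr <- fits$M0$tree
  for (m in setdiff(models, "M0"))
    fits[[m]] <- fit_site_model(m, tr, caln, freqs, K, n_restarts, seed,
                                fix_kappa = fits$M0$kappa)
  out <- fits
  if (all(c("M0", "M3") %in% names(fits)))
    out$lrt_m0_m3 <- lrt(fits$M3, fits$M0)
  if (all(c("M7", "M8") %in% names(fits)))
    out$lrt_m7_m8 <- lrt(fits$M8, fits$M7)
  out
}

#' Likelihood-ratio test between nested fits
#'
#' \eqn{2\Delta\ell = 2(\ell_{alt} - \ell_{null})} compared to a
#' chi-squared distribution. The statistic is reported as computed;
#' a negative value (optimizer failure on nested models) is flagged.
#'
#' @param alt,null Fits (any objects with \code{lnL} and
#'   \code{np_omega}), or numeric log-likelihoods.
#' @param df Degrees of freedom (default: difference in the number of
#'   omega-distribution parameters).
#' @param mixture Use the 50:50 mixture of point mass and chi-squared
#'   (branch-site convention).
#' @return List of class \code{lrt_result}: \code{stat}, \code{df},
#'   \code{p_value}, \code{suspect} (negative statistic flag).
#' @export
lrt <- function(alt, null, df = NULL, mixture = FALSE) {
  l1 <- if (is.numeric(alt)) alt else alt$lnL
  l0 <- if (is.numeric(null)) null else null$lnL
  if (is.null(df)) {
    if (is.numeric(alt) || is.numeric(null))
      stop("df must be given when raw likelihoods are supplied")
    df <- alt$np_omega - null$np_omega
  }
  stopifnot(df >= 1L)
  stat <- 2 * (l1 - l0)
  p <- stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
  if (mixture) p <- 0.5 * p
  structure(list(stat = stat, df = df, p_value = p, suspect = stat < 0),
            class = "lrt_result")
}

#' Fit branch-site model A and its null
#'
#' Four site classes: (0) omega0 <= 1 everywhere, (1) omega = 1
#' everywhere, (2a) background omega0 / foreground omega2 >= 1, (2b)
#' background 1 / foreground omega2. The null model fixes omega2 = 1;
#' the LRT has one degree of freedom. Branch lengths are held fixed
#' (use the M0 estimates).
#'
#' @param tree \code{phylo} with branch lengths.
#' @param caln \code{codon_alignment}.
#' @param foreground_tips Tips whose spanning clade (including its
#'   stem edge) forms the foreground.
#' @param freqs,n_restarts,seed As in \code{\link{fit_site_model}}.
#' @return List with \code{alt} and \code{null} \code{site_model_fit}
#'   objects (each carrying class omegas for background/foreground)
#'   and \code{lrt} (mixture convention).
#' @export
fit_branch_site <- function(tree, caln, foreground_tips,
                            freqs = c("F3x4", "uniform"),
                            n_restarts = 3L, seed = 1L) {
  freqs <- match.arg(freqs)
  fg_edges <- clade_edges(tree, foreground_tips)
  if (length(fg_edges) >= nrow(tree$edge))
    stop("foreground covers the whole tree")
  X <- encode_codon_alignment(caln)
  pi <- if (freqs == "F3x4") f3x4_freqs(caln) else NULL

  unpack <- function(par, null) {
    kappa <- .clamp(exp(par[1]), 0.01, 100)
    w0 <- .clamp(stats::plogis(par[2]), 1e-6, 1)
    w2 <- if (null) 1 else 1 + .clamp(exp(par[5]), 1e-8, 999)
    pr <- .softmax(c(par[3], par[4], 0))  # p0, p1, p2
    p2a <- pr[3] * pr[1] / (pr[1] + pr[2])
    p2b <- pr[3] * pr[2] / (pr[1] + pr[2])
    list(kappa = kappa,
         bg = c(w0, 1, w0, 1), fg = c(w0, 1, w2, w2),
         weights = c(pr[1], pr[2], p2a, p2b),
         params = c(omega0 = w0, omega2 = w2, p0 = pr[1], p1 = pr[2],
                    p2a = p2a, p2b = p2b))
  }
  fit_one <- function(null) {
    np <- if (null) 4L else 5L
    objective <- function(par) {
      mp <- unpack(par, null)
      ll <- try(codon_loglik(tree, X, mp$bg, mp$weights, mp$kappa, pi,
                             fg_omegas = mp$fg, fg_edges = fg_edges)$lnL,
                silent = TRUE)
      if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
      -ll
    }
    base <- c(log(2), stats::qlogis(0.2), 1.5, 0.5, log(1))[seq_len(np)]
    if (!null) base <- c(log(2), stats::qlogis(0.2), 1.5, 0.5, log(1))
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(seed + r - 1L)
      start <- if (r == 1L) base else base + stats::rnorm(length(base), 0, 0.4)
      f <- try(stats::nlminb(start, objective,
                             control = list(iter.max = 400L, eval.max = 1500L)),
               silent = TRUE)
      if (inherits(f, "try-error")) next
      if (is.null(best) || f$objective < best$objective) best <- f
    }
    if (is.null(best)) stop("branch-site optimization failed")
    mp <- unpack(if (null) c(best$par, 0) else best$par, null)
    ll <- codon_loglik(tree, X, mp$bg, mp$weights, mp$kappa, pi,
                       fg_omegas = mp$fg, fg_edges = fg_edges)
    structure(list(
      model = if (null) "branch-site A null" else "branch-site A",
      lnL = -best$objective, kappa = mp$kappa,
      omegas = mp$fg, bg_omegas = mp$bg, weights = mp$weights,
      params = mp$params, np_omega = if (null) 3L else 4L,
      tree = tree, pi = pi, site_loglik = ll$site_loglik,
      site_mix_loglik = ll$site_mix_loglik, caln = caln,
      fg_edges = fg_edges,
      convergence = best$convergence == 0), class = "site_model_fit")
  }
  alt <- fit_one(FALSE)
  null <- fit_one(TRUE)
  list(alt = alt, null = null,
       lrt = lrt(alt, null, df = 1L, mixture = TRUE))
}

#' @noRd
.map_to_reference <- function(caln, ref_id, sites) {
  if (is.null(ref_id))
    return(list(ref_site = rep(NA_integer_, length(sites)),
                ref_aa = rep(NA_character_, length(sites))))
  if (!ref_id %in% names(caln)) stop("reference id not in alignment")
  codons <- split_codons(unclass(caln)[[match(ref_id, names(caln))]])
  ungapped <- cumsum(codons != "---")
  ref_site <- ifelse(codons[sites] == "---", NA_integer_, ungapped[sites])
  aa <- translate_codon(codons[sites])
  list(ref_site = ref_site, ref_aa = ifelse(is.na(aa), NA_character_, aa))
}

#' Empirical-Bayes posterior probabilities of positive selection
#'
#' NEB evaluates class posteriors at the maximum-likelihood estimates:
#' the posterior of class k at a site is proportional to the class
#' weight times the site likelihood under that class. BEB (available
#' for M8) averages the NEB calculation over an 8-point grid per
#' parameter on (p0, p, q, omega_s) with a uniform prior, weighting
#' grid points by their data likelihood. Sites are called at the 0.95
#' and 0.99 posterior tiers. For models without an omega > 1 class
#' the call list is empty and a note is attached.
#'
#' @param fit \code{site_model_fit}.
#' @param method \code{"NEB"} or \code{"BEB"}.
#' @param ref_id Optional alignment row used to express site
#'   coordinates in that sequence's residue numbering.
#' @param grid_n Grid points per parameter for BEB.
#' @return data.frame of class \code{site_selection_calls}: columns
#'   \code{site}, \code{ref_site}, \code{ref_aa}, \code{posterior},
#'   \code{tier}; the full posterior vector for all sites is in
#'   attribute \code{"posterior_all"}.
#' @export
eb_site_posteriors <- function(fit, method = c("NEB", "BEB"), ref_id = NULL,
                               grid_n = 8L) {
  method <- match.arg(method)
  pos_class <- which(fit$omegas > 1)
  nsite <- ncol(fit$site_loglik)
  empty <- function(note) {
    out <- data.frame(site = integer(), ref_site = integer(),
                      ref_aa = character(), posterior = numeric(),
                      tier = character())
    attr(out, "note") <- note
    attr(out, "posterior_all") <- rep(0, nsite)
    class(out) <- c("site_selection_calls", class(out))
    out
  }
  if (!length(pos_class))
    return(empty("model has no omega > 1 class"))
  if (method == "BEB") {
    if (fit$model != "M8")
      stop("grid BEB is implemented for M8; use NEB for other models")
    post <- .beb_m8_posterior(fit, grid_n)
  } else {
    sl <- fit$site_loglik
    lw <- log(fit$weights)
    num <- sl + lw
    mx <- apply(num, 2L, max)
    pmat <- exp(sweep(num, 2L, mx))
    pmat <- sweep(pmat, 2L, colSums(pmat), "/")
    post <- colSums(pmat[pos_class, , drop = FALSE])
  }
  called <- which(post > 0.95)
  refm <- .map_to_reference(fit$caln, ref_id, called)
  out <- data.frame(site = called,
                    ref_site = refm$ref_site,
                    ref_aa = refm$ref_aa,
                    posterior = post[called],
                    tier = ifelse(post[called] > 0.99, "p>0.99", "p>0.95"),
                    stringsAsFactors = FALSE)
  attr(out, "posterior_all") <- post
  class(out) <- c("site_selection_calls", class(out))
  out
}

# Grid BEB for M8: uniform prior over an 8^4 grid on
# (p0, p, q, omega_s); grid points weighted by their marginal data
# likelihood; site posterior of the selection class averaged over the
# grid.
#' @noRd
.beb_m8_posterior <- function(fit, grid_n = 8L) {
  X <- encode_codon_alignment(fit$caln)
  tree <- fit$tree
  pi <- fit$pi
  kappa <- fit$kappa
  K <- if (!is.null(fit$K)) fit$K else 10L
  mid <- (2 * seq_len(grid_n) - 1) / (2 * grid_n)
  p0_grid <- mid
  pq_grid <- exp(seq(log(0.1), log(50), length.out = grid_n))
  w_grid <- 1 + 10 * mid          # omega_s in (1, 11)
  nsite <- ncol(fit$site_loglik)

  site_ll <- function(omegas) {
    eigs <- lapply(omegas, function(w) codon_eig_cached(kappa, w, pi))
    prune_site_loglik(tree, X, eigs)
  }
  # log mean_k exp site loglik for each (p, q)
  M <- array(NA_real_, c(grid_n, grid_n, nsite))
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    sl <- site_ll(beta_class_omegas(pq_grid[i], pq_grid[j], K))
    mx <- apply(sl, 2L, max)
    M[i, j, ] <- mx + log(colMeans(exp(sweep(sl, 2L, mx))))
  }
  W <- matrix(NA_real_, grid_n, nsite)
  for (k in seq_len(grid_n)) W[k, ] <- site_ll(w_grid[k])[1L, ]

  log_post_num <- rep(-Inf, nsite)  # accumulators over grid
  log_norm <- rep(-Inf, nsite)
  grid_logw <- c()
  combos <- expand.grid(a = seq_len(grid_n), i = seq_len(grid_n),
                        j = seq_len(grid_n), k = seq_len(grid_n))
  # first pass: grid marginal likelihoods
  site_mix <- vector("list", nrow(combos))
  logpos <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    p0 <- p0_grid[combos$a[r]]
    m <- M[combos$i[r], combos$j[r], ]
    w <- W[combos$k[r], ]
    l1 <- log(p0) + m
    l2 <- log(1 - p0) + w
    mx <- pmax(l1, l2)
    mix <- mx + log(exp(l1 - mx) + exp(l2 - mx))
    site_mix[[r]] <- mix
    logpos[[r]] <- l2 - mix
    grid_logw[r] <- sum(mix)
  }
  grid_logw <- grid_logw - max(grid_logw)
  gw <- exp(grid_logw); gw <- gw / sum(gw)
  post <- rep(0, nsite)
  for (r in seq_len(nrow(combos)))
    if (gw[r] > 0) post <- post + gw[r] * exp(logpos[[r]])
  pmin(post, 1)
}
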