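test_that("the GY94 generator has the defining structural properties", {
  pi <- as.numeric(stats::rgamma(61, 5)); pi <- pi / sum(pi)
  Q <- build_rate_matrix(kappa = 3, omega = 0.4, pi = pi)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  # detailed balance (reversibility)
  expect_equal(max(abs(pi * Q - t(pi * Q))), 0, tolerance = 1e-12)
  # unit expected substitution flux
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # multi-position changes are forbidden
  sc <- burpevol:::sense_codons()
  ndiff <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  set.seed(1)
  for (k in 1:50) {
    ij <- sample(61, 2)
    if (ndiff(sc[ij[1]], sc[ij[2]]) > 1) expect_equal(Q[ij[1], ij[2]], 0)
  }
  # hand-checked rate ratios on a uniform-frequency matrix:
  Qu <- build_rate_matrix(kappa = 3, omega = 0.4)
  # TTT->TTC (Phe->Phe, C<->T transition) vs TTT->TTA (Phe->Leu transversion)
  expect_equal(Qu["TTT", "TTC"] / Qu["TTT", "TTA"], 3 / 0.4)
  # TTT->TCT (nonsyn transition) vs TTT->TAT (nonsyn transversion)
  expect_equal(Qu["TTT", "TCT"] / Qu["TTT", "TAT"], 3)
  # GGA->GGC (Gly->Gly, transversion): baseline synonymous transversion
  expect_equal(Qu["GGA", "GGC"], Qu["TTT", "TTA"] / 0.4)
})

test_that("pruning equals brute-force enumeration and elementary cases", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.15,c:0.3);")
  set.seed(8)
  sim <- simulate_codon_alignment(tr, 3, omegas = c(0.2, 1.5),
                                  weights = c(0.6, 0.4), kappa = 2.5, seed = 8)
  X <- encode_codon_alignment(sim$caln)
  got <- codon_loglik(tr, sim$caln, omegas = c(0.2, 1.5),
                      weights = c(0.6, 0.4), kappa = 2.5)
  want <- oracle_loglik_3taxa(tr, X, omegas = c(0.2, 1.5),
                              weights = c(0.6, 0.4), kappa = 2.5)
  expect_equal(got$lnL, want, tolerance = 1e-8)
  # two identical sequences at branch length zero: lnL = sum log pi
  tr2 <- ape::read.tree(text = "(a:0,b:0,c:0);")
  row <- "ATGAAA"
  caln2 <- structure(c(a = row, b = row, c = row), class = "codon_alignment")
  ll2 <- codon_loglik(tr2, caln2, omegas = 1, weights = 1, kappa = 2)
  expect_equal(ll2$lnL, 2 * log(1 / 61), tolerance = 1e-9)
  # gaps are missing data
  caln3 <- structure(c(a = "ATG---", b = "ATGAAA", c = "ATGAAA"),
                     class = "codon_alignment")
  expect_true(is.finite(codon_loglik(tr, caln3, 1, 1, 2)$lnL))
})

test_that("likelihood is invariant to rerooting and padded classes", {
  set.seed(12)
  tr <- ape::rtree(5, br = function(n) runif(n, 0.05, 0.3))
  sim <- simulate_codon_alignment(tr, 40, omegas = 0.3, weights = 1,
                                  kappa = 2, seed = 12)
  base <- codon_loglik(tr, sim$caln, 0.3, 1, 2)$lnL
  rerooted <- ape::unroot(ape::root(tr, outgroup = tr$tip.label[1],
                                    resolve.root = TRUE))
  expect_equal(codon_loglik(rerooted, sim$caln, 0.3, 1, 2)$lnL, base,
               tolerance = 1e-8)
  padded <- codon_loglik(tr, sim$caln, omegas = c(0.3, 5),
                         weights = c(1, 0), kappa = 2)$lnL
  expect_equal(padded, base, tolerance = 1e-10)
})

test_that("M0 recovers simulation truth and nests inside M3", {
  set.seed(2)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.3))
  sim <- simulate_codon_alignment(tr, 200, omegas = 0.2, weights = 1,
                                  kappa = 2, seed = 11)
  f0 <- fit_site_model("M0", tr, sim$caln, freqs = "uniform",
                       n_restarts = 1, seed = 1)
  expect_true(f0$convergence)
  expect_gt(f0$omegas, 0.1); expect_lt(f0$omegas, 0.35)
  expect_gt(f0$kappa, 1.3); expect_lt(f0$kappa, 3)
  f3 <- fit_site_model("M3", f0$tree, sim$caln, freqs = "uniform",
                       n_restarts = 1, seed = 1, fix_kappa = f0$kappa)
  # M0 is a special case of M3
  expect_gte(f3$lnL, f0$lnL - 1e-4)
  expect_equal(sum(f3$weights), 1)
})

test_that("LRT arithmetic, degrees of freedom and flags are correct", {
  r <- lrt(-20403.3, -20918.0, df = 4)
  expect_equal(r$stat, 1029.4)
  expect_lt(r$p_value, 1e-10)
  neg <- lrt(-100.2, -100.0, df = 1)
  expect_true(neg$suspect)
  expect_error(lrt(-1, -2), "df must be given")
  half <- lrt(-99, -100, df = 1, mixture = TRUE)
  expect_equal(half$p_value, 0.5 * stats::pchisq(2, 1, lower.tail = FALSE))
})

test_that("branch-site model A fits both hypotheses with sane classes", {
  set.seed(30)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.08, 0.25))
  fg_tips <- tr$tip.label[1:2]
  fg <- clade_edges(tr, fg_tips)
  sim <- simulate_codon_alignment(tr, 120, omegas = c(0.2, 1),
                                  weights = c(0.8, 0.2), kappa = 2,
                                  fg_omegas = c(0.2, 4), fg_edges = fg,
                                  seed = 31)
  bs <- fit_branch_site(tr, sim$caln, fg_tips, freqs = "uniform",
                        n_restarts = 1, seed = 1)
  expect_equal(sum(bs$alt$weights), 1, tolerance = 1e-8)
  expect_equal(sum(bs$null$weights), 1, tolerance = 1e-8)
  expect_equal(unname(bs$null$params["omega2"]), 1)
  expect_gte(bs$alt$lnL, bs$null$lnL - 1e-4)
  expect_equal(bs$lrt$df, 1L)
  expect_error(fit_branch_site(tr, sim$caln, tr$tip.label), "whole tree")
})

test_that("posterior class probabilities follow the mixture identities", {
  # degenerate case: all classes identical => posterior equals prior
  set.seed(40)
  tr <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.2))
  sim <- simulate_codon_alignment(tr, 30, omegas = 0.5, weights = 1,
                                  kappa = 2, seed = 41)
  fit <- list(model = "M3", omegas = c(0.5, 0.5, 1.2),
              weights = c(0.3, 0.5, 0.2),
              site_loglik = codon_loglik(tr, sim$caln,
                                         omegas = c(0.5, 0.5, 1.2),
                                         weights = c(0.3, 0.5, 0.2),
                                         kappa = 2)$site_loglik,
              caln = sim$caln)
  class(fit) <- "site_model_fit"
  calls <- eb_site_posteriors(fit, "NEB")
  post <- attr(calls, "posterior_all")
  # identical omega classes share likelihood: the 1.2 class posterior is
  # determined by relative weights whenever its likelihood equals theirs
  sl <- fit$site_loglik
  same <- abs(sl[1, ] - sl[3, ]) < 1e-12
  expect_true(all(abs(post[same] - 0.2) < 1e-10))
  # model without a positive class yields an empty call set with a note
  fit2 <- fit; fit2$omegas <- c(0.2, 0.5, 0.9)
  calls2 <- eb_site_posteriors(fit2, "NEB")
  expect_equal(nrow(calls2), 0L)
  expect_match(attr(calls2, "note"), "no omega > 1")
})
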