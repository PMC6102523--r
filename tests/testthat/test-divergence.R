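# helper: simulate per-site substitution counts from the type-I
# mixture (theta of the sites draw independent gamma rates per
# cluster; the rest share one rate)
sim_theta1_counts <- function(n_sites, theta, alpha = 1, dA = 2, dB = 2) {
  div <- stats::runif(n_sites) < theta
  xa <- integer(n_sites); xb <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    if (div[i]) {
      ra <- stats::rgamma(1, alpha, alpha); rb <- stats::rgamma(1, alpha, alpha)
    } else {
      ra <- rb <- stats::rgamma(1, alpha, alpha)
    }
    xa[i] <- stats::rpois(1, dA * ra); xb[i] <- stats::rpois(1, dB * rb)
  }
  list(xa = xa, xb = xb, divergent = div)
}

test_that("Fitch counts match exhaustive small-parsimony enumeration", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln <- as_aa_alignment(c(a = "AAC", b = "AAC", c = "AGC", d = "AGT"))
  counts <- site_substitution_counts(aln, tr)
  expect_equal(counts[1], 0L)   # invariant column
  expect_equal(counts[2], 1L)   # two states split across the root
  set.seed(14)
  tr2 <- ape::rtree(6)
  for (rep in 1:25) {
    col <- sample(c("A", "R", "N", "D"), 6, replace = TRUE)
    names(col) <- tr2$tip.label
    aln2 <- as_aa_alignment(stats::setNames(col, tr2$tip.label))
    expect_equal(site_substitution_counts(aln2, tr2)[1],
                 oracle_fitch(col, tr2))
  }
  # all-gap columns are excluded as NA
  aln3 <- as_aa_alignment(c(a = "A-", b = "A-", c = "A-", d = "A-"))
  expect_true(is.na(site_substitution_counts(aln3, tr)[2]))
})

test_that("theta-I is near zero for shared rates and recovers planted values", {
  set.seed(50)
  shared <- sim_theta1_counts(600, theta = 0)
  est0 <- estimate_theta1(shared$xa, shared$xb)
  expect_lte(est0$theta, 0.05)
  planted <- sim_theta1_counts(600, theta = 0.5, alpha = 0.7)
  est <- estimate_theta1(planted$xa, planted$xb)
  expect_gt(est$theta, 0.3); expect_lt(est$theta, 0.7)
  expect_true(est$se >= 0 || is.na(est$se))
  expect_true(all(est$qk >= 0 & est$qk <= 1, na.rm = TRUE))
  # cluster-label swap invariance
  est_sw <- estimate_theta1(planted$xb, planted$xa)
  expect_equal(est_sw$theta, est$theta, tolerance = 1e-4)
  expect_error(estimate_theta1(rep(0L, 10), rep(0L, 10)), "invariant")
})

test_that("divergence-state posteriors rank truly divergent sites higher", {
  set.seed(51)
  planted <- sim_theta1_counts(800, theta = 0.4, alpha = 0.5, dA = 3, dB = 3)
  est <- estimate_theta1(planted$xa, planted$xb)
  expect_gt(mean(est$qk[planted$divergent]), mean(est$qk[!planted$divergent]))
})

test_that("divergence posteriors grow with count disparity at fixed totals", {
  q_of <- function(xa, xb)
    burpevol:::.theta1_loglik(xa, xb, theta = 0.3, alpha = 1,
                              dA = 2, dB = 2)$q
  qs <- c(q_of(5L, 5L), q_of(7L, 3L), q_of(9L, 1L), q_of(10L, 0L))
  expect_true(all(diff(qs) > 0))
})

test_that("theta-I LRT holds its size under the null", {
  set.seed(52)
  rej <- 0L
  for (r in 1:50) {
    x <- sim_theta1_counts(120, theta = 0)
    e <- try(estimate_theta1(x$xa, x$xb), silent = TRUE)
    if (!inherits(e, "try-error") && e$p_value < 0.05) rej <- rej + 1L
  }
  expect_lte(rej / 50, 0.1)
})

test_that("theta-II measures radical excess on consensus patterns", {
  mk <- function(rows) as_aa_alignment(rows)
  # identical consensi: no divergence signal
  rows <- stats::setNames(rep("KDSAV", 4), paste0("a", 1:4))
  rows2 <- stats::setNames(rep("KDSAV", 4), paste0("b", 1:4))
  t0 <- estimate_theta2(mk(rows), mk(rows2), n_boot = 50)
  expect_equal(t0$theta, 0, tolerance = 1e-12)
  # planted radical shifts (class-crossing flips) at conserved sites,
  # on a residue-diverse background so the expected radical rate < 1
  consA <- paste0(rep(c("K", "R", "D", "E", "S", "T", "A", "V", "L", "I"), 2),
                  collapse = "")
  bA <- strsplit(consA, "")[[1]]
  bB <- bA; bB[1:4] <- c("D", "E", "A", "V")   # pos->neg, polar->hydro
  A <- mk(stats::setNames(rep(consA, 5), paste0("a", 1:5)))
  B <- mk(stats::setNames(rep(paste0(bB, collapse = ""), 5), paste0("b", 1:5)))
  t1 <- estimate_theta2(A, B, n_boot = 50)
  expect_gt(t1$theta, 0)
  top <- order(t1$qk, decreasing = TRUE)[1:4]
  expect_setequal(top, 1:4)
  # conservative (within-class) differences fall below the background
  # expectation and drive the moment estimate negative
  bC <- bA; bC[1:4] <- c("R", "K", "E", "D")
  C <- mk(stats::setNames(rep(paste0(bC, collapse = ""), 5), paste0("c", 1:5)))
  t2 <- estimate_theta2(A, C, n_boot = 50)
  expect_lt(t2$theta, 0)
})

test_that("the cluster wrapper reports called sites with reference coords", {
  set.seed(53)
  sim <- simulate_family(sim_config(seed = 6, subfamily_sizes = c(6L, 6L)))
  fam <- sim$truth$subfamily
  tree <- nj_tree(protein_distance(sim$alignment))
  a_ids <- fam$id[fam$subfamily == "SF1"][1:5]
  b_ids <- fam$id[fam$subfamily == "SF2"][1:5]
  fd <- functional_divergence(sim$alignment, tree, a_ids, b_ids,
                              ref_id = a_ids[1])
  expect_s3_class(fd$theta1, "divergence_estimate")
  expect_true(is.finite(fd$theta1$theta))
  expect_true(all(fd$sites_type1$qk > 0.95))
  expect_error(functional_divergence(sim$alignment, tree, a_ids[1:3], b_ids),
               ">= 4")
})
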