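# Independent oracles used to validate the package implementations.
# These deliberately use different algorithms/code paths from R/.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Brute-force BURP pattern matcher: enumerate every start position and
# every admissible spacer combination; return the leftmost match with
# minimal spacers (spacer 2 minimized before spacer 3), or NULL.
oracle_burp_scan <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  for (s in seq_len(max(n - 56L, 0L))) {
    for (s2 in 23:27) {
      for (s3 in 23:26) {
        p1 <- s                      # dyad 1 C
        p2 <- p1 + 2L + 10L          # dyad 2 C
        p3 <- p2 + 2L + s2           # dyad 3 C
        p4 <- p3 + 2L + s3           # dyad 4 C
        pw <- p4 + 2L + 8L           # terminal W
        if (pw > n) next
        if (ch[p1] == "C" && ch[p1 + 1L] == "H" &&
            ch[p2] == "C" && ch[p2 + 1L] == "H" &&
            ch[p3] == "C" && ch[p3 + 1L] == "H" &&
            ch[p4] == "C" && ch[p4 + 1L] == "H" &&
            ch[pw] == "W")
          return(list(start = p1, end = pw, s2 = s2, s3 = s3))
      }
    }
  }
  NULL
}

# Independent NG86: recursive pathway enumeration with its own site
# counting, built directly on the genetic code.
.ogc <- Biostrings::GENETIC_CODE
oracle_translate <- function(codon) unname(.ogc[gsub("U", "T", codon)])

oracle_ng86 <- function(codons1, codons2) {
  stopifnot(length(codons1) == length(codons2))
  bases <- c("T", "C", "A", "G")
  syn_sites <- function(codon) {
    total <- 0
    for (p in 1:3) {
      s <- 0L; v <- 0L
      for (b in setdiff(bases, substr(codon, p, p))) {
        mut <- codon; substr(mut, p, p) <- b
        if (oracle_translate(mut) == "*") next
        v <- v + 1L
        if (oracle_translate(mut) == oracle_translate(codon)) s <- s + 1L
      }
      if (v > 0L) total <- total + s / v
    }
    total
  }
  paths <- function(c1, c2) {
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) return(c(0, 0))
    acc <- list()
    walk <- function(cur, remaining, s, ns, blocked) {
      if (!length(remaining)) {
        acc[[length(acc) + 1L]] <<- c(s, ns, blocked)
        return(invisible())
      }
      for (i in seq_along(remaining)) {
        p <- remaining[i]
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        hit_stop <- oracle_translate(nxt) == "*"
        same <- oracle_translate(nxt) == oracle_translate(cur)
        walk(nxt, remaining[-i], s + same, ns + !same, blocked || hit_stop)
      }
    }
    walk(c1, dp, 0L, 0L, FALSE)
    m <- do.call(rbind, acc)
    ok <- m[, 3] == 0
    if (any(ok)) colMeans(m[ok, 1:2, drop = FALSE])
    else colMeans(m[, 1:2, drop = FALSE])
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(codons1)) {
    S <- S + (syn_sites(codons1[k]) + syn_sites(codons2[k])) / 2
    sn <- paths(codons1[k], codons2[k])
    Sd <- Sd + sn[1]; Nd <- Nd + sn[2]
  }
  N <- 3 * length(codons1) - S
  jc <- function(p) if (1 - 4 * p / 3 <= 0) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       Ks = jc(Sd / S), Ka = jc(Nd / N))
}

# Brute-force mixture codon likelihood for <= 3 tips: the single
# internal node is summed explicitly; transition matrices come from a
# series-based matrix exponential, independent of the package's
# spectral code.
oracle_expm <- function(Q, t) {
  A <- Q * t
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (k in 1:60) {
    term <- term %*% A / k
    P <- P + term
  }
  P
}

oracle_loglik_3taxa <- function(tree, X, omegas, weights, kappa, pi = NULL) {
  stopifnot(length(tree$tip.label) <= 3L, tree$Nnode == 1L)
  n <- 61L
  if (is.null(pi)) pi <- rep(1 / n, n)
  X <- X[tree$tip.label, , drop = FALSE]
  total <- 0
  for (site in seq_len(ncol(X))) {
    mix <- 0
    for (k in seq_along(omegas)) {
      Q <- build_rate_matrix(kappa, omegas[k], pi)
      lik <- 0
      for (r in seq_len(n)) {
        term <- pi[r]
        for (e in seq_len(nrow(tree$edge))) {
          tipno <- tree$edge[e, 2L]
          P <- oracle_expm(Q, tree$edge.length[e])
          obs <- X[tipno, site]
          term <- term * if (is.na(obs)) 1 else P[r, obs]
        }
        lik <- lik + term
      }
      mix <- mix + weights[k] * lik
    }
    total <- total + log(mix)
  }
  unname(total)
}

# Exhaustive small-parsimony oracle: minimum changes over all internal
# labelings drawn from the observed states.
oracle_fitch <- function(tips, tree) {
  # tips: named character vector of single residues (or "-")
  states <- unique(tips[tips != "-"])
  if (length(states) <= 1L) return(0L)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  combos <- expand.grid(rep(list(states), length(internal)),
                        stringsAsFactors = FALSE)
  best <- Inf
  lab <- character(ntip + tree$Nnode)
  lab[seq_len(ntip)] <- tips[tree$tip.label]
  for (r in seq_len(nrow(combos))) {
    lab[internal] <- unlist(combos[r, ])
    chg <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      a <- lab[tree$edge[e, 1L]]; b <- lab[tree$edge[e, 2L]]
      if (b != "-" && a != b) chg <- chg + 1L
    }
    best <- min(best, chg)
  }
  best
}

# Position-by-position protein distance counting oracle
oracle_pdist <- function(r1, r2) {
  a <- strsplit(r1, "")[[1]]; b <- strsplit(r2, "")[[1]]
  keep <- a != "-" & b != "-"
  sum(a[keep] != b[keep]) / sum(keep)
}

random_codon_row <- function(n, exclude_stops = TRUE) {
  sc <- if (exclude_stops) burpevol:::sense_codons() else burpevol:::all_codons()
  paste0(sample(sc, n, replace = TRUE), collapse = "")
}
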