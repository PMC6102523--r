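# Internal codon bookkeeping shared by the NG86, 4DTv and GY94 code.
# Everything here is derived once from the standard genetic code and cached.

.codon_cache <- new.env(parent = emptyenv())

BASES <- c("T", "C", "A", "G")
PURINES <- c("A", "G")
STOP_AA <- "*"

#' @noRd
all_codons <- function() {
  if (is.null(.codon_cache$codons)) {
    .codon_cache$codons <- apply(expand.grid(p3 = BASES, p2 = BASES, p1 = BASES)[, 3:1],
                                 1L, paste0, collapse = "")
    names(.codon_cache$codons) <- NULL
  }
  .codon_cache$codons
}

#' @noRd
codon_aa <- function() {
  if (is.null(.codon_cache$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_cache$aa <- unname(gc[all_codons()])
  }
  .codon_cache$aa
}

#' @noRd
sense_codons <- function() {
  if (is.null(.codon_cache$sense)) {
    .codon_cache$sense <- all_codons()[codon_aa() != STOP_AA]
  }
  .codon_cache$sense
}

#' @noRd
sense_aa <- function() codon_aa()[codon_aa() != STOP_AA]

#' @noRd
translate_codon <- function(codon) {
  aa <- codon_aa()
  names(aa) <- all_codons()
  unname(aa[codon])
}

#' Translate an ungapped coding sequence
#' @noRd
translate_cds <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- translate_codon(codons)
  aa[is.na(aa)] <- "X"  # N-containing codons
  paste0(aa, collapse = "")
}

#' @noRd
is_transition <- function(b1, b2) {
  (b1 %in% PURINES) == (b2 %in% PURINES) & b1 != b2
}

# NG86 synonymous site fraction per sense codon: at each position the
# fraction of the possible single-base changes that are synonymous,
# with changes to stop codons excluded from both numerator and
# denominator, so S + N = 3 per codon.
#' @noRd
ng86_sites <- function() {
  if (!is.null(.codon_cache$sites)) return(.codon_cache$sites)
  sc <- sense_codons()
  aa <- sense_aa()
  names(aa) <- sc
  all_aa <- codon_aa(); names(all_aa) <- all_codons()
  S <- numeric(length(sc)); names(S) <- sc
  for (cd in sc) {
    s_tot <- 0
    for (pos in 1:3) {
      base <- substr(cd, pos, pos)
      syn <- 0L; valid <- 0L
      for (b in setdiff(BASES, base)) {
        mut <- cd
        substr(mut, pos, pos) <- b
        if (all_aa[mut] == STOP_AA) next
        valid <- valid + 1L
        if (all_aa[mut] == all_aa[cd]) syn <- syn + 1L
      }
      if (valid > 0L) s_tot <- s_tot + syn / valid
    }
    S[cd] <- s_tot
  }
  .codon_cache$sites <- S
  S
}

# Pathway-averaged synonymous/nonsynonymous difference counts between
# every pair of sense codons (NG86): enumerate all orders of the
# single-base steps, drop pathways passing through a stop codon, and
# average the per-step classifications over the remaining pathways.
# If every pathway is blocked by a stop (does not happen for sense
# pairs under the standard code, kept for safety) all pathways are used.
#' @noRd
ng86_paths <- function() {
  if (!is.null(.codon_cache$paths)) return(.codon_cache$paths)
  sc <- sense_codons()
  n <- length(sc)
  all_aa <- codon_aa(); names(all_aa) <- all_codons()
  Sd <- matrix(0, n, n, dimnames = list(sc, sc))
  Nd <- matrix(0, n, n, dimnames = list(sc, sc))
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                            c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  for (i in seq_len(n)) {
    ci <- strsplit(sc[i], "")[[1]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- strsplit(sc[j], "")[[1]]
      diff_pos <- which(ci != cj)
      k <- length(diff_pos)
      if (k == 1L) {
        syn <- all_aa[sc[i]] == all_aa[sc[j]]
        Sd[i, j] <- as.numeric(syn); Nd[i, j] <- as.numeric(!syn)
        next
      }
      ord <- perms[[as.character(k)]]
      sd_tot <- 0; nd_tot <- 0; n_ok <- 0L
      sd_all <- 0; nd_all <- 0
      for (p in seq_len(nrow(ord))) {
        cur <- ci; s <- 0; ns <- 0; blocked <- FALSE
        for (step in ord[p, ]) {
          nxt <- cur
          nxt[diff_pos[step]] <- cj[diff_pos[step]]
          a1 <- all_aa[paste0(cur, collapse = "")]
          a2 <- all_aa[paste0(nxt, collapse = "")]
          if (a2 == STOP_AA) blocked <- TRUE
          if (a1 == a2) s <- s + 1 else ns <- ns + 1
          cur <- nxt
        }
        sd_all <- sd_all + s; nd_all <- nd_all + ns
        if (!blocked) { sd_tot <- sd_tot + s; nd_tot <- nd_tot + ns; n_ok <- n_ok + 1L }
      }
      if (n_ok > 0L) {
        Sd[i, j] <- sd_tot / n_ok; Nd[i, j] <- nd_tot / n_ok
      } else {
        Sd[i, j] <- sd_all / nrow(ord); Nd[i, j] <- nd_all / nrow(ord)
      }
    }
  }
  .codon_cache$paths <- list(Sd = Sd, Nd = Nd)
  .codon_cache$paths
}

# Two-base prefixes whose four codons all encode the same amino acid
#' @noRd
fourfold_prefixes <- function() {
  if (is.null(.codon_cache$ff)) {
    all_aa <- codon_aa(); names(all_aa) <- all_codons()
    pref <- apply(expand.grid(p2 = BASES, p1 = BASES)[, 2:1], 1L, paste0, collapse = "")
    keep <- vapply(pref, function(p) {
      aas <- all_aa[paste0(p, BASES)]
      all(aas != STOP_AA) && length(unique(aas)) == 1L
    }, logical(1))
    .codon_cache$ff <- pref[keep]
  }
  .codon_cache$ff
}

#' @noRd
split_codons <- function(row) {
  n <- nchar(row) %/% 3L
  substring(row, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# half-up rounding to `digits` decimals (matches the print convention
# used for duplication ages)
#' @noRd
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
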