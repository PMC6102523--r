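# Protein-guided codon alignments and pairwise codon distance
# statistics: Nei-Gojobori (1986) Ka/Ks and the fourfold-degenerate
# transversion proportion (4DTv).

#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned protein row is mapped onto its coding sequence: every
#' residue becomes its source codon and every gap becomes \code{---}.
#' A trailing stop codon on the CDS is trimmed before mapping. The
#' translation of every codon is checked against the aligned residue
#' (the unknown residue X matches any codon).
#'
#' @param protein_aln \code{aa_alignment}.
#' @param cds data.frame with columns \code{id}, \code{sequence}, ids
#'   covering the alignment rows.
#' @return Named character vector of gapped codon rows, class
#'   \code{codon_alignment}, with attribute \code{n_codon_columns}.
#' @export
back_translate <- function(protein_aln, cds) {
  ids <- names(protein_aln)
  miss <- setdiff(ids, cds$id)
  if (length(miss)) stop("no CDS for: ", paste(miss, collapse = ", "))
  out <- character(length(ids))
  for (k in seq_along(ids)) {
    row <- unclass(protein_aln)[[k]]
    aa <- strsplit(row, "")[[1]]
    s <- toupper(cds$sequence[match(ids[k], cds$id)])
    if (nchar(s) %% 3L != 0L)
      stop("CDS length of '", ids[k], "' is not a multiple of 3")
    codons <- split_codons(s)
    last_aa <- translate_codon(codons[length(codons)])
    if (!is.na(last_aa) && last_aa == STOP_AA) codons <- codons[-length(codons)]
    n_res <- sum(aa != "-")
    if (length(codons) != n_res)
      stop("'", ids[k], "': ", n_res, " aligned residues but ",
           length(codons), " codons")
    tr <- translate_codon(codons)
    tr[is.na(tr)] <- "X"
    res <- aa[aa != "-"]
    bad <- which(tr != res & res != "X" & tr != "X")
    if (length(bad))
      stop("'", ids[k], "': codon ", bad[1L], " translates to '",
           tr[bad[1L]], "' but alignment has '", res[bad[1L]], "'")
    filled <- rep("---", length(aa))
    filled[aa != "-"] <- codons
    out[k] <- paste0(filled, collapse = "")
  }
  names(out) <- ids
  structure(out, n_codon_columns = nchar(out[[1L]]) %/% 3L,
            class = "codon_alignment")
}

#' @noRd
pair_codon_columns <- function(row1, row2) {
  c1 <- split_codons(toupper(row1))
  c2 <- split_codons(toupper(row2))
  if (length(c1) != length(c2)) stop("codon rows differ in length")
  keep <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE) &
          !grepl("N", c1, fixed = TRUE) & !grepl("N", c2, fixed = TRUE)
  # in-frame stop codons: column excluded and noted
  aa <- codon_aa(); names(aa) <- all_codons()
  stopcol <- rep(FALSE, length(c1))
  stopcol[keep] <- aa[c1[keep]] == STOP_AA | aa[c2[keep]] == STOP_AA
  if (any(stopcol)) {
    message(sum(stopcol), " in-frame stop codon column(s) excluded")
    keep <- keep & !stopcol
  }
  list(c1 = c1[keep], c2 = c2[keep])
}

#' Nei-Gojobori (1986) pairwise synonymous/nonsynonymous rates
#'
#' Codon columns containing a gap (or N) in either row are excluded
#' (pairwise deletion). Synonymous site counts average the synonymous
#' fractions of the two codons; difference counts average equally over
#' all substitution pathways that avoid stop codons. The Jukes-Cantor
#' correction \eqn{d = -3/4 \log(1 - 4p/3)} converts the proportions
#' ps and pn into Ks and Ka; when the log argument is non-positive the
#' estimate is saturated and flagged.
#'
#' @param row1,row2 Gapped codon strings of equal length.
#' @return List of class \code{pairwise_rates}: \code{Ks}, \code{Ka},
#'   \code{S}, \code{N}, \code{Sd}, \code{Nd}, \code{ps}, \code{pn},
#'   \code{n_codons}, \code{saturated}.
#' @export
ng86_rates <- function(row1, row2) {
  pc <- pair_codon_columns(row1, row2)
  nc <- length(pc$c1)
  if (nc == 0L) stop("no comparable codon columns")
  sites <- ng86_sites()
  S <- sum((sites[pc$c1] + sites[pc$c2]) / 2)
  N <- 3 * nc - S
  paths <- ng86_paths()
  idx <- cbind(match(pc$c1, sense_codons()), match(pc$c2, sense_codons()))
  Sd <- sum(paths$Sd[idx])
  Nd <- sum(paths$Nd[idx])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) NA_real_ else -0.75 * log(arg)
  }
  Ks <- jc(ps); Ka <- jc(pn)
  structure(list(Ks = Ks, Ka = Ka, S = S, N = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn, n_codons = nc,
                 saturated = is.na(Ks) || is.na(Ka)),
            class = "pairwise_rates")
}

#' Fourfold-degenerate transversion proportion (4DTv)
#'
#' Eligible columns are those where both codons share the same first
#' two bases and that prefix defines a fourfold-degenerate codon
#' family. The raw statistic is the proportion of eligible columns
#' whose third positions differ by a transversion. With no eligible
#' column the value is undefined (NA, flagged). An optional corrected
#' variant applies the Kimura transversion correction
#' \eqn{-\log(1-2Q)/2}, which can exceed the raw proportion's [0, 0.5]
#' working range once sites saturate.
#'
#' @param row1,row2 Gapped codon strings of equal length.
#' @param corrected Apply the transversion distance correction
#'   (default \code{FALSE}: report the raw proportion).
#' @return List of class \code{d4dtv}: \code{d4dtv},
#'   \code{fourfold_sites}, \code{fourfold_transversions},
#'   \code{undefined}, \code{saturated}.
#' @export
d4dtv <- function(row1, row2, corrected = FALSE) {
  pc <- pair_codon_columns(row1, row2)
  if (length(pc$c1) == 0L) stop("no comparable codon columns")
  pre1 <- substr(pc$c1, 1L, 2L)
  pre2 <- substr(pc$c2, 1L, 2L)
  eligible <- pre1 == pre2 & pre1 %in% fourfold_prefixes()
  n4 <- sum(eligible)
  if (n4 == 0L)
    return(structure(list(d4dtv = NA_real_, fourfold_sites = 0L,
                          fourfold_transversions = 0L,
                          undefined = TRUE, saturated = FALSE),
                     class = "d4dtv"))
  b1 <- substr(pc$c1[eligible], 3L, 3L)
  b2 <- substr(pc$c2[eligible], 3L, 3L)
  tv <- sum(is_transition(b1, b2) == FALSE & b1 != b2)
  val <- tv / n4
  sat <- FALSE
  if (corrected) {
    arg <- 1 - 2 * val
    if (arg <= 0) { val <- NA_real_; sat <- TRUE }
    else val <- -0.5 * log(arg)
  }
  structure(list(d4dtv = val, fourfold_sites = n4,
                 fourfold_transversions = as.integer(tv),
                 undefined = FALSE, saturated = sat),
            class = "d4dtv")
}

#' Pairwise rate table for a whole codon alignment
#'
#' Applies \code{\link{ng86_rates}} and \code{\link{d4dtv}} to every
#' pair of rows.
#'
#' @param caln \code{codon_alignment}.
#' @return data.frame with one row per unordered pair.
#' @export
codon_pair_table <- function(caln) {
  ids <- names(caln)
  n <- length(ids)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- ng86_rates(caln[[i]], caln[[j]])
      f <- d4dtv(caln[[i]], caln[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        idA = ids[i], idB = ids[j], Ks = r$Ks, Ka = r$Ka,
        S = r$S, N = r$N, d4dtv = f$d4dtv,
        fourfold_sites = f$fourfold_sites,
        saturated = r$saturated, d4dtv_undefined = f$undefined,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
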