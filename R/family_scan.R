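# Identification and curation of BURP domain-containing proteins.
#
# The family is defined by a conserved C-terminal pattern of four
# cysteine-histidine (CH) dyads with constrained spacers and a terminal
# tryptophan:  C H X10 C H X23-27 C H X23-26 C H X8 W,
# where X is any residue.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

.burp_regex <- "(CH).{10}(CH).{23,27}?(CH).{23,26}?(CH).{8}(W)"

#' Scan a protein sequence for the BURP C-terminal domain
#'
#' Finds the leftmost occurrence of the conserved BURP pattern
#' \code{C H X10 C H X23-27 C H X23-26 C H X8 W}. Spacer matching is
#' lazy, so among overlapping matches the leftmost one with minimal
#' spacers is reported. The anchor residues (C, H, W) must be literal;
#' the unknown residue code \code{X} is allowed only in spacer
#' positions. The two additional conserved cysteines of the domain are
#' annotated when present inside the matched span but are not required
#' for a match.
#'
#' @param sequence Amino-acid string (20 standard residues plus X).
#' @param id Optional sequence identifier used in error messages.
#' @return A list of class \code{burp_domain_hit} with elements
#'   \code{start}, \code{end} (1-based inclusive), \code{complete},
#'   and \code{motif_spans} (data.frame of position/label for the four
#'   CH dyads, the terminal W and any extra cysteines), or \code{NULL}
#'   if the pattern is absent.
#' @examples
#' seq <- paste0("CH", strrep("A", 10), "CH", strrep("A", 25),
#'               "CH", strrep("A", 24), "CH", strrep("A", 8), "W")
#' scan_burp_domain(seq)$complete
#' @export
scan_burp_domain <- function(sequence, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("empty protein sequence", if (!is.null(id)) paste0(" for '", id, "'"))
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(AA20, "X"))
  if (length(bad))
    stop("invalid residue(s) ", paste(sQuote(bad), collapse = ", "),
         if (!is.null(id)) paste0(" in '", id, "'"))
  m <- regexpr(.burp_regex, sequence, perl = TRUE)
  if (m == -1L) return(NULL)
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  cs <- as.integer(attr(m, "capture.start"))
  spans <- data.frame(
    position = cs,
    label = c("CH1", "CH2", "CH3", "CH4", "W"),
    stringsAsFactors = FALSE
  )
  # extra conserved cysteines: C residues inside the span that are not
  # part of the four dyads
  dom <- substr(sequence, start, end)
  cpos <- start - 1L + which(strsplit(dom, "")[[1]] == "C")
  extra <- setdiff(cpos, cs[1:4])
  if (length(extra))
    spans <- rbind(spans, data.frame(position = extra,
                                     label = paste0("C_extra", seq_along(extra))))
  spans <- spans[order(spans$position), , drop = FALSE]
  rownames(spans) <- NULL
  structure(list(start = start, end = end, complete = TRUE,
                 motif_spans = spans),
            class = "burp_domain_hit")
}

#' Keep the longest isoform per locus
#'
#' One record is retained per \code{locus_id}, the one with the longest
#' protein; ties are broken by the lexicographically smallest \code{id}
#' so the choice is deterministic.
#'
#' @param records data.frame with columns \code{id}, \code{locus_id},
#'   \code{sequence} (and any others, which are carried along).
#' @return The filtered data.frame, one row per locus.
#' @export
select_longest_isoform <- function(records) {
  stopifnot(all(c("id", "locus_id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) return(records)
  ord <- order(records$locus_id, -nchar(records$sequence), records$id)
  records <- records[ord, , drop = FALSE]
  out <- records[!duplicated(records$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test a coding sequence for a complete open reading frame
#'
#' A complete ORF starts with ATG, ends with a stop codon, has length a
#' multiple of three, and contains no internal stop. Genes failing this
#' test are treated as pseudogene candidates by \code{\link{build_catalog}}.
#' Codons containing N are treated as non-stop; their presence is
#' flagged in the \code{"ambiguous"} attribute of the result.
#'
#' @param sequence Nucleotide string (case-insensitive, alphabet ACGTN).
#' @return Logical scalar with attribute \code{ambiguous}.
#' @export
check_complete_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid nucleotide(s): ", paste(sQuote(bad), collapse = ", "))
  n <- nchar(s)
  ok <- TRUE
  ambiguous <- FALSE
  if (n == 0L || n %% 3L != 0L || substr(s, 1L, 3L) != "ATG") {
    ok <- FALSE
  } else {
    codons <- split_codons(s)
    ambiguous <- any(grepl("N", codons, fixed = TRUE))
    stops <- codons %in% c("TAA", "TAG", "TGA")
    if (!stops[length(stops)] || any(stops[-length(stops)])) ok <- FALSE
  }
  structure(ok, ambiguous = ambiguous)
}

#' Build a curated family catalog
#'
#' Joins proteins to their coding sequences, keeps the longest isoform
#' per locus, drops incomplete ORFs (pseudogene rule) and proteins
#' without a complete BURP domain, and reports every exclusion.
#'
#' @param proteins data.frame with columns \code{id}, \code{locus_id},
#'   \code{species}, \code{sequence}.
#' @param cds data.frame with columns \code{id}, \code{sequence};
#'   ids must match the protein ids (optionally through \code{id_map}).
#' @param id_map Optional two-column data.frame (\code{protein_id},
#'   \code{cds_id}) when protein and CDS files use different ids.
#' @return An object of class \code{burp_catalog}: list with elements
#'   \code{table} (id, species, locus_id, domain_start, domain_end,
#'   complete), \code{excluded} (id, reason), \code{proteins},
#'   \code{cds} (curated data.frames).
#' @export
build_catalog <- function(proteins, cds, id_map = NULL) {
  stopifnot(all(c("id", "locus_id", "sequence") %in% names(proteins)),
            all(c("id", "sequence") %in% names(cds)))
  if (!"species" %in% names(proteins)) proteins$species <- NA_character_
  if (nrow(proteins) == 0L) {
    warning("empty protein input: returning empty catalog")
    return(structure(list(
      table = data.frame(id = character(), species = character(),
                         locus_id = character(), domain_start = integer(),
                         domain_end = integer(), complete = logical()),
      excluded = data.frame(id = character(), reason = character()),
      proteins = proteins, cds = cds[0, , drop = FALSE]),
      class = "burp_catalog"))
  }
  if (!is.null(id_map)) {
    idx <- match(proteins$id, id_map$protein_id)
    if (anyNA(idx)) stop("id_map misses protein ids: ",
                         paste(proteins$id[is.na(idx)], collapse = ", "))
    cds_ids <- id_map$cds_id[idx]
  } else cds_ids <- proteins$id
  unpaired <- setdiff(cds_ids, cds$id)
  if (length(unpaired))
    stop("no CDS record for: ", paste(unpaired, collapse = ", "))
  proteins$cds_id <- cds_ids

  excluded <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  kept <- select_longest_isoform(proteins)
  dropped <- setdiff(proteins$id, kept$id)
  if (length(dropped))
    excluded <- rbind(excluded, data.frame(id = dropped, reason = "redundant_isoform"))
  proteins <- kept

  cds_seq <- cds$sequence[match(proteins$cds_id, cds$id)]
  orf_ok <- vapply(cds_seq, function(s) as.logical(check_complete_orf(s)), logical(1))
  if (any(!orf_ok))
    excluded <- rbind(excluded, data.frame(id = proteins$id[!orf_ok],
                                           reason = "incomplete_orf"))
  proteins <- proteins[orf_ok, , drop = FALSE]
  cds_seq <- cds_seq[orf_ok]

  hits <- lapply(proteins$sequence, scan_burp_domain)
  has_dom <- !vapply(hits, is.null, logical(1))
  if (any(!has_dom))
    excluded <- rbind(excluded, data.frame(id = proteins$id[!has_dom],
                                           reason = "incomplete_domain"))
  tab <- data.frame(
    id = proteins$id,
    species = proteins$species,
    locus_id = proteins$locus_id,
    domain_start = vapply(hits, function(h) if (is.null(h)) NA_integer_ else h$start, integer(1)),
    domain_end = vapply(hits, function(h) if (is.null(h)) NA_integer_ else h$end, integer(1)),
    complete = has_dom,
    stringsAsFactors = FALSE
  )
  keep <- has_dom
  out_cds <- data.frame(id = proteins$id[keep], sequence = cds_seq[keep],
                        stringsAsFactors = FALSE)
  structure(list(table = tab[keep, , drop = FALSE],
                 excluded = excluded,
                 proteins = proteins[keep, , drop = FALSE],
                 cds = out_cds),
            class = "burp_catalog")
}

#' @export
print.burp_catalog <- function(x, ...) {
  cat("BURP family catalog:", nrow(x$table), "members,",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$excluded))
    print(table(x$excluded$reason))
  invisible(x)
}

#' Write a catalog and its curated FASTA pair to disk
#'
#' @param catalog A \code{burp_catalog}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "catalog.tsv")
  utils::write.table(catalog$table, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  exc <- file.path(dir, "excluded.tsv")
  utils::write.table(catalog$excluded, exc, sep = "\t", quote = FALSE, row.names = FALSE)
  paa <- file.path(dir, "family_proteins.fasta")
  pnt <- file.path(dir, "family_cds.fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(catalog$proteins$sequence, catalog$proteins$id)), paa)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(catalog$cds$sequence, catalog$cds$id)), pnt)
  invisible(c(tsv, exc, paa, pnt))
}

#' Read a protein or CDS FASTA into a data.frame
#'
#' The locus id defaults to the sequence id with a trailing isoform
#' suffix (\code{.1}, \code{.2}, ...) removed.
#'
#' @param path FASTA file.
#' @param type \code{"protein"} or \code{"dna"}.
#' @param species Optional species label recycled across records.
#' @return data.frame with columns id, locus_id, species, sequence.
#' @export
read_fasta_df <- function(path, type = c("protein", "dna"), species = NA_character_) {
  type <- match.arg(type)
  ss <- if (type == "protein") Biostrings::readAAStringSet(path)
        else Biostrings::readDNAStringSet(path)
  id <- sub("\\s.*$", "", names(ss))
  data.frame(id = id,
             locus_id = sub("\\.\\d+$", "", id),
             species = species,
             sequence = as.character(ss),
             stringsAsFactors = FALSE)
}
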