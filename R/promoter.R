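# Upstream promoter extraction and table-driven cis-element scanning.

IUPAC_CODES <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")

#' Read a cis-element definition table
#'
#' Tab-delimited columns: name, pattern (IUPAC nucleotide codes),
#' category. A starter table with literature consensus patterns for
#' the common hormone- and stress-responsive elements ships with the
#' package (see \code{system.file("extdata", "cis_elements.tsv",
#' package = "burpevol")}); those patterns are simplified consensi,
#' not the scanning matrices of any promoter database.
#'
#' @param path TSV file.
#' @return data.frame with columns name, pattern, category.
#' @export
read_cis_elements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("name", "pattern", "category") %in% names(df)))
  df$pattern <- toupper(df$pattern)
  bad <- vapply(strsplit(df$pattern, ""), function(ch)
    any(!ch %in% IUPAC_CODES), logical(1))
  if (any(bad))
    stop("invalid IUPAC pattern(s): ", paste(df$name[bad], collapse = ", "))
  df
}

#' Extract the upstream promoter window of a gene
#'
#' For a plus-strand gene the window of length \code{window} ending at
#' \code{start - 1}; for a minus-strand gene the reverse complement of
#' the window starting at \code{end + 1}. The window is anchored at
#' the translation start, and truncated (and flagged) at chromosome
#' edges.
#'
#' @param genome Named \code{DNAStringSet} (or named character vector)
#'   of chromosome sequences.
#' @param gene List or one-row data.frame with \code{chromosome},
#'   \code{start}, \code{end}, \code{strand}.
#' @param window Window length in bp (default 1500).
#' @return Character promoter sequence with attribute
#'   \code{truncated} (logical).
#' @export
extract_upstream <- function(genome, gene, window = 1500L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chrom <- as.character(gene$chromosome)
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not in genome")
  chrlen <- Biostrings::width(genome[chrom])
  strand <- as.character(gene$strand)
  if (strand == "+") {
    to <- gene$start - 1L
    from <- max(1L, to - window + 1L)
    if (to < 1L) return(structure("", truncated = TRUE))
    s <- as.character(Biostrings::subseq(genome[[chrom]], from, to))
  } else {
    from <- gene$end + 1L
    to <- min(chrlen, from + window - 1L)
    if (from > chrlen) return(structure("", truncated = TRUE))
    s <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[[chrom]], from, to)))
  }
  structure(s, truncated = nchar(s) < window)
}

#' Scan a sequence for cis-element occurrences
#'
#' All (including overlapping) matches of each IUPAC pattern are
#' reported on both strands. Positions are 1-based starts in the
#' forward coordinates of the scanned sequence; a minus-strand hit at
#' position p means the reverse complement of the pattern starts
#' there.
#'
#' @param seq Nucleotide string (a promoter window).
#' @param defs data.frame of element definitions (name, pattern,
#'   category).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return data.frame with columns element, position, strand.
#' @export
scan_elements <- function(seq, defs, both_strands = TRUE) {
  stopifnot(all(c("name", "pattern") %in% names(defs)))
  bad <- vapply(strsplit(toupper(defs$pattern), ""), function(ch)
    any(!ch %in% IUPAC_CODES), logical(1))
  if (any(bad))
    stop("invalid IUPAC pattern(s): ", paste(defs$name[bad], collapse = ", "))
  subject <- Biostrings::DNAString(toupper(seq))
  L <- length(subject)
  rows <- list()
  for (r in seq_len(nrow(defs))) {
    pat <- Biostrings::DNAString(defs$pattern[r])
    hits <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    if (length(hits))
      rows[[length(rows) + 1L]] <- data.frame(
        element = defs$name[r],
        position = Biostrings::start(hits), strand = "+",
        stringsAsFactors = FALSE)
    if (both_strands) {
      rpat <- Biostrings::reverseComplement(pat)
      rhits <- Biostrings::matchPattern(rpat, subject, fixed = FALSE)
      if (length(rhits))
        rows[[length(rows) + 1L]] <- data.frame(
          element = defs$name[r],
          position = Biostrings::start(rhits), strand = "-",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(element = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$element, out$position, out$strand), , drop = FALSE]
}

#' Scan the promoters of a set of genes
#'
#' @param promoters Named character vector gene id -> upstream window.
#' @param defs Element definition data.frame.
#' @param both_strands Scan both strands.
#' @return data.frame with columns gene, element, position, strand.
#' @export
scan_promoters <- function(promoters, defs, both_strands = TRUE) {
  rows <- lapply(names(promoters), function(g) {
    h <- scan_elements(promoters[[g]], defs, both_strands)
    if (nrow(h)) cbind(gene = g, h, stringsAsFactors = FALSE) else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(gene = character(), element = character(),
                      position = integer(), strand = character()))
  do.call(rbind, rows)
}

#' Summarize element counts per subfamily
#'
#' Produces the "count/members" presentation: for every element, the
#' total number of occurrences in each subfamily over the number of
#' subfamily members, plus family-wide totals and mean copies per
#' gene.
#'
#' @param hits data.frame from \code{\link{scan_promoters}}.
#' @param assignment data.frame with columns \code{id},
#'   \code{subfamily} covering every scanned gene.
#' @return List of class \code{element_summary}: \code{counts}
#'   (subfamily x element matrix), \code{members} (named vector),
#'   \code{display} (character matrix "count/members"),
#'   \code{mean_copies} (per element, family-wide).
#' @export
summarize_elements <- function(hits, assignment) {
  stopifnot(all(c("id", "subfamily") %in% names(assignment)))
  if (nrow(hits) && length(setdiff(hits$gene, assignment$id)))
    stop("hits contain genes without subfamily assignment")
  subfams <- sort(unique(assignment$subfamily))
  elements <- sort(unique(hits$element))
  members <- table(factor(assignment$subfamily, levels = subfams))
  counts <- matrix(0L, length(subfams), max(length(elements), 1L),
                   dimnames = list(subfams, if (length(elements)) elements else "none"))
  if (nrow(hits)) {
    sf <- assignment$subfamily[match(hits$gene, assignment$id)]
    tb <- table(factor(sf, levels = subfams),
                factor(hits$element, levels = elements))
    counts <- matrix(as.integer(tb), nrow = length(subfams),
                     dimnames = dimnames(tb))
  }
  n_fam <- nrow(assignment)
  display <- matrix(paste0(counts, "/", as.integer(members)[row(counts)]),
                    nrow = nrow(counts), dimnames = dimnames(counts))
  total_row <- paste0(colSums(counts), "/", n_fam)
  structure(list(counts = counts, members = members, display = display,
                 total = colSums(counts), total_display = total_row,
                 mean_copies = colSums(counts) / n_fam),
            class = "element_summary")
}

#' @export
print.element_summary <- function(x, ...) {
  tab <- rbind(x$display, Total = x$total_display)
  print(tab, quote = FALSE)
  invisible(x)
}
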