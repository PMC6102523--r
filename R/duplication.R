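# Tandem/segmental duplication classification, molecular-clock dating
# (T = Ks / 2*lambda) and exon-structure summaries.

#' Read gene models from a GFF3 file
#'
#' Parses \code{gene} and \code{exon} features (1-based inclusive)
#' into a gene table with per-gene exon interval lists. Exons are
#' attached to genes through their \code{Parent}/\code{ID} chain or,
#' failing that, by coordinate containment.
#'
#' @param path GFF3 file.
#' @return data.frame with columns \code{id}, \code{chromosome},
#'   \code{start}, \code{end}, \code{strand} and a list-column
#'   \code{exons} of two-column matrices (start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  # map exon -> gene through mRNA parents when present
  parent_of <- function(p) vapply(p, function(x) if (length(x)) x[[1]] else NA_character_, character(1))
  exon_parent <- parent_of(exons$Parent)
  if (nrow(mrna)) {
    m2g <- stats::setNames(parent_of(mrna$Parent), mrna$ID)
    via_m <- m2g[exon_parent]
    exon_gene <- ifelse(is.na(via_m), exon_parent, via_m)
  } else exon_gene <- exon_parent
  out <- data.frame(id = genes$ID, chromosome = as.character(genes$seqnames),
                    start = genes$start, end = genes$end,
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  out$exons <- lapply(out$id, function(g) {
    e <- exons[which(exon_gene == g), , drop = FALSE]
    if (nrow(e) == 0L) return(matrix(numeric(), ncol = 2L,
                                     dimnames = list(NULL, c("start", "end"))))
    e <- e[order(e$start), , drop = FALSE]
    cbind(start = e$start, end = e$end)
  })
  out
}

#' Number of exons of a gene model
#'
#' @param gene One row of a gene-model data.frame (or a list with an
#'   \code{exons} matrix).
#' @return Integer exon count.
#' @export
exon_count <- function(gene) {
  ex <- if (is.data.frame(gene)) gene$exons[[1L]] else gene$exons
  if (is.null(ex) || nrow(ex) == 0L)
    stop("gene has no annotated exons")
  nrow(ex)
}

#' Detect tandem-duplicated family pairs
#'
#' Tandem duplicates are family genes on the same chromosome separated
#' by at most \code{max_intervening} annotated genes (any gene,
#' including other family members, counts as intervening). Gene order
#' is defined by start coordinate with ties broken by id.
#'
#' @param genes Gene-model data.frame of the whole annotation
#'   (family and non-family genes), with columns \code{id},
#'   \code{chromosome}, \code{start}.
#' @param family_ids Character vector of family member ids.
#' @param max_intervening Maximum number of intervening genes
#'   (inclusive bound; default 10).
#' @return data.frame with columns \code{idA}, \code{idB},
#'   \code{chromosome}, \code{intervening}, \code{mode}.
#' @export
tandem_pairs <- function(genes, family_ids, max_intervening = 10L) {
  stopifnot(all(c("id", "chromosome", "start") %in% names(genes)))
  missing <- setdiff(family_ids, genes$id)
  if (length(missing))
    stop("family id(s) missing from annotation: ", paste(missing, collapse = ", "))
  rows <- list()
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    g <- g[order(g$start, g$id), , drop = FALSE]
    fam_rank <- which(g$id %in% family_ids)
    if (length(fam_rank) < 2L) next
    for (a in seq_len(length(fam_rank) - 1L)) {
      for (b in (a + 1L):length(fam_rank)) {
        intervening <- fam_rank[b] - fam_rank[a] - 1L
        if (intervening <= max_intervening) {
          pr <- sort(c(g$id[fam_rank[a]], g$id[fam_rank[b]]))
          rows[[length(rows) + 1L]] <- data.frame(
            idA = pr[1L], idB = pr[2L], chromosome = chr,
            intervening = intervening, mode = "tandem",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(idA = character(), idB = character(),
                      chromosome = character(), intervening = integer(),
                      mode = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$chromosome, out$idA, out$idB), , drop = FALSE]
}

#' Read a collinearity anchor file
#'
#' Tab-delimited with columns block_id, geneA, geneB, Ks (header
#' optional; malformed rows raise an error with the line number).
#'
#' @param path Anchor TSV.
#' @return data.frame with columns \code{block_id}, \code{geneA},
#'   \code{geneB}, \code{ks}.
#' @export
read_anchors <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[4L])))
  if (has_header) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad))
    stop("malformed anchor row at line ", bad[1L] + has_header)
  ks <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 4L)))
  if (anyNA(ks))
    stop("non-numeric Ks at line ", which(is.na(ks))[1L] + has_header)
  if (any(ks < 0)) stop("negative Ks in anchor file")
  data.frame(block_id = vapply(parts, `[`, character(1), 1L),
             geneA = vapply(parts, `[`, character(1), 2L),
             geneB = vapply(parts, `[`, character(1), 3L),
             ks = ks, stringsAsFactors = FALSE)
}

#' Detect segmentally duplicated family pairs from anchor blocks
#'
#' Anchors with Ks above \code{ks_max} are discarded; blocks retaining
#' fewer than \code{min_anchors} anchors are discarded entirely. Every
#' family gene pair anchored in a surviving block is reported with the
#' mean and standard deviation of Ks over that block's surviving
#' anchors.
#'
#' @param anchors data.frame as from \code{\link{read_anchors}}.
#' @param family_ids Character vector of family member ids.
#' @param ks_max Saturation cutoff on per-anchor Ks (default 1.0).
#' @param min_anchors Minimum surviving anchors per block (default 3).
#' @return data.frame with columns \code{idA}, \code{idB},
#'   \code{block_id}, \code{ks_mean}, \code{ks_sd}, \code{n_anchors},
#'   \code{mode}.
#' @export
segmental_pairs <- function(anchors, family_ids, ks_max = 1.0, min_anchors = 3L) {
  keep <- anchors$ks <= ks_max
  anchors <- anchors[keep, , drop = FALSE]
  rows <- list()
  for (blk in unique(anchors$block_id)) {
    a <- anchors[anchors$block_id == blk, , drop = FALSE]
    if (nrow(a) < min_anchors) next
    fam <- a[a$geneA %in% family_ids & a$geneB %in% family_ids, , drop = FALSE]
    if (nrow(fam) == 0L) next
    for (r in seq_len(nrow(fam))) {
      pr <- sort(c(fam$geneA[r], fam$geneB[r]))
      rows[[length(rows) + 1L]] <- data.frame(
        idA = pr[1L], idB = pr[2L], block_id = blk,
        ks_mean = mean(a$ks), ks_sd = stats::sd(a$ks),
        n_anchors = nrow(a), mode = "segmental", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(idA = character(), idB = character(),
                      block_id = character(), ks_mean = numeric(),
                      ks_sd = numeric(), n_anchors = integer(),
                      mode = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Date a duplication event with a synonymous molecular clock
#'
#' \eqn{T = Ks / (2 \lambda)}, converted to million years and rounded
#' half-up to one decimal for reporting; the raw value is returned
#' alongside.
#'
#' @param ks_mean Mean synonymous distance of the pair.
#' @param lambda Clock rate in synonymous substitutions/site/year.
#' @return List with \code{age_mya} (rounded, 1 decimal) and
#'   \code{age_mya_raw}.
#' @export
date_pair <- function(ks_mean, lambda) {
  stopifnot(all(lambda > 0), all(ks_mean >= 0))
  raw <- ks_mean / (2 * lambda) / 1e6
  list(age_mya = round_half_up(raw, 1L), age_mya_raw = raw)
}

#' Default species synonymous clock rates
#'
#' Literature clock rates used for the family: soybean 6.1e-9,
#' Brassica 1.4e-8, Arabidopsis 1.5e-8 synonymous
#' substitutions/site/year.
#' @return Named numeric vector.
#' @export
default_clock_rates <- function() {
  c(soybean = 6.1e-9, brassica = 1.4e-8, arabidopsis = 1.5e-8)
}

#' Date a table of segmental pairs
#'
#' @param pairs data.frame from \code{\link{segmental_pairs}} (or any
#'   table with \code{ks_mean}) plus a \code{species} column.
#' @param clock_rates Named vector species -> lambda.
#' @return The input with \code{age_mya} and \code{age_mya_raw} added.
#' @export
date_segmental_pairs <- function(pairs, clock_rates = default_clock_rates()) {
  missing <- setdiff(unique(pairs$species), names(clock_rates))
  if (length(missing))
    stop("no clock rate for species: ", paste(missing, collapse = ", "))
  lam <- clock_rates[pairs$species]
  aged <- date_pair(pairs$ks_mean, lam)
  pairs$age_mya <- aged$age_mya
  pairs$age_mya_raw <- aged$age_mya_raw
  pairs
}
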