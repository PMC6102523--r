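# Synthetic gene families with known ground truth.
#
# The generator reuses the GY94 machinery of the selection module to
# evolve codon sequences along a subfamily-structured gene tree, so
# recovery tests are model-consistent. A BURP-pattern core (four CH
# dyads with fixed spacers and the terminal W) is held invariant in
# every non-decoy protein; tandem and segmental duplicates are planted
# at calibrated synonymous depths; 1500-bp upstream regions carry
# planted cis-elements at recorded positions.

#' Configuration for the synthetic family generator
#'
#' Defaults describe a desk-scale family: four subfamilies of six
#' genes split over two species, 150-codon coding sequences evolved
#' under kappa = 2 and purifying omega = 0.2, one tandem and one
#' segmental duplication, a handful of curation decoys, and two
#' elements planted twice each in every promoter.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param subfamily_sizes Genes per subfamily.
#' @param species Species labels (genes are split across them).
#' @param seq_codons Coding length in codons (>= 110 so the 76-residue
#'   domain core fits).
#' @param kappa Transition/transversion ratio of the simulation model.
#' @param omega Per-subfamily nonsynonymous/synonymous ratios
#'   (recycled).
#' @param crown_depth Expected substitutions/codon from subfamily root
#'   to tip.
#' @param backbone_length Branch length separating subfamilies.
#' @param tandem_ks,segmental_ks Synonymous depths of the planted
#'   duplications (NA to omit).
#' @param tandem_intervening Filler genes between the tandem pair.
#' @param n_anchors Anchor pairs in the planted segmental block.
#' @param anchor_ks_sd Spread of per-anchor Ks around the block depth.
#' @param window Promoter window length (bp).
#' @param planted_elements data.frame(name, pattern, copies) of
#'   elements planted per family gene (default: two ABRE and two MBS
#'   copies).
#' @param promoter_alphabet Background alphabet for promoter filler
#'   (restrict to exclude pattern letters for zero-background tests).
#' @param background_gc Background GC content of promoter/intergenic
#'   filler.
#' @param n_incomplete,n_extra_isoforms,n_pseudogenes Decoy counts.
#' @param clock_rates Named lambda per species
#'   (synonymous substitutions/site/year).
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       subfamily_sizes = c(6L, 6L, 6L, 6L),
                       species = c("speciesA", "speciesB"),
                       seq_codons = 150L,
                       kappa = 2,
                       omega = 0.2,
                       crown_depth = 0.25,
                       backbone_length = 0.9,
                       tandem_ks = 0.2,
                       segmental_ks = 0.5,
                       tandem_intervening = 3L,
                       n_anchors = 5L,
                       anchor_ks_sd = 0.05,
                       window = 1500L,
                       planted_elements = data.frame(
                         name = c("ABRE", "MBS"),
                         pattern = c("ACGTGGC", "CAACTG"),
                         copies = c(2L, 2L),
                         stringsAsFactors = FALSE),
                       promoter_alphabet = c("A", "C", "G", "T"),
                       background_gc = 0.4,
                       n_incomplete = 2L,
                       n_extra_isoforms = 2L,
                       n_pseudogenes = 1L,
                       clock_rates = c(speciesA = 6.1e-9, speciesB = 1.5e-8)) {
  cfg <- as.list(environment())
  stopifnot(seq_codons >= 110L, all(subfamily_sizes >= 2L),
            length(species) >= 1L, crown_depth > 0)
  if (length(cfg$omega) < length(subfamily_sizes))
    cfg$omega <- rep(cfg$omega, length.out = length(subfamily_sizes))
  class(cfg) <- "sim_config"
  cfg
}

# Anchor codon offsets of the invariant domain core (0-based within
# the core): C of each dyad (H follows), then the terminal W.
# Spacers 10/25/24/8 -> dyads at 0, 12, 39, 65; W at 75; 76 codons.
.core_layout <- function() {
  ch <- c(0L, 12L, 39L, 65L)
  list(C = ch, H = ch + 1L, W = 75L, length = 76L)
}

#' @noRd
.force_core <- function(codon_rows, core_start) {
  lay <- .core_layout()
  for (off in lay$C) {
    pos <- (core_start + off) * 3L + 1L
    substr(codon_rows, pos, pos + 2L) <- rep("TGC", length(codon_rows))
    pos <- (core_start + off + 1L) * 3L + 1L
    substr(codon_rows, pos, pos + 2L) <- rep("CAC", length(codon_rows))
  }
  pos <- (core_start + lay$W) * 3L + 1L
  substr(codon_rows, pos, pos + 2L) <- rep("TGG", length(codon_rows))
  substr(codon_rows, 1L, 3L) <- rep("ATG", length(codon_rows))
  codon_rows
}

#' Calibrate a branch length for a target NG86 Ks
#'
#' Finds the total branch length t (expected substitutions per codon
#' under the scaled GY94 generator) such that the expected NG86
#' synonymous distance between the two ends equals \code{ks}. The
#' expectation uses the exact codon-pair distribution
#' \eqn{\pi_i P_{ij}(t)}.
#'
#' @param ks Target synonymous distance.
#' @param kappa,omega,pi Simulation model parameters.
#' @return Branch length t.
#' @export
ks_to_branch_length <- function(ks, kappa = 2, omega = 0.2, pi = NULL) {
  if (ks == 0) return(0)
  Q <- build_rate_matrix(kappa, omega, pi)
  pivec <- attr(Q, "pi")
  eg <- codon_eig(Q)
  sites <- ng86_sites()
  paths <- ng86_paths()
  sc <- sense_codons()
  Smean <- outer(sites[sc], sites[sc], "+") / 2
  expected_ks <- function(t) {
    J <- pivec * codon_pmat(eg, t)
    S <- sum(J * Smean)
    Sd <- sum(J * paths$Sd)
    ps <- Sd / S
    arg <- 1 - 4 * ps / 3
    if (arg <= 0) return(100)  # saturated: finite sentinel for uniroot
    -0.75 * log(arg)
  }
  stats::uniroot(function(t) expected_ks(t) - ks, c(1e-6, 20),
                 tol = 1e-8)$root
}

#' @noRd
.random_dna <- function(n, alphabet = c("A", "C", "G", "T"), gc = 0.4) {
  w <- stats::setNames(rep(0, 4), c("A", "C", "G", "T"))
  w[c("G", "C")] <- gc / 2
  w[c("A", "T")] <- (1 - gc) / 2
  w <- w[alphabet]; w <- w / sum(w)
  paste0(sample(alphabet, n, replace = TRUE, prob = w), collapse = "")
}

#' @noRd
.scale_to_depth <- function(tr, depth) {
  d <- max(ape::node.depth.edgelength(tr))
  if (d > 0) tr$edge.length <- tr$edge.length * depth / d
  tr
}

# evolve a subtree from a fixed root state vector; returns tip states
#' @noRd
.evolve_subtree <- function(tree, root_states, eig) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nsites <- length(root_states)
  states <- matrix(NA_integer_, ntip + tree$Nnode, nsites)
  root <- tree$edge[nrow(tree$edge), 1L]
  states[root, ] <- root_states
  for (e in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    P <- codon_pmat(eig, tree$edge.length[e])
    ps <- states[par, ]
    for (s in unique(ps)) {
      w <- which(ps == s)
      states[child, w] <- sample.int(61L, length(w), replace = TRUE, prob = P[s, ])
    }
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' @noRd
.evolve_branch <- function(states, t, eig) {
  P <- codon_pmat(eig, t)
  out <- states
  for (s in unique(states)) {
    w <- which(states == s)
    out[w] <- sample.int(61L, length(w), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate a complete synthetic gene family
#'
#' Produces every input the analysis pipeline consumes, plus truth
#' tables: protein and CDS records (with isoform/pseudogene/incomplete
#' decoys), the family protein alignment (the simulation is
#' indel-free, so aligned length equals sequence length), gene models
#' and a genome with promoter windows carrying planted elements, a
#' collinearity anchor table with one planted segmental block, and
#' the true subfamily labels, duplication pairs and element positions.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List of class \code{sim_family}; see Details in the
#'   package vignette.
#' @export
simulate_family <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sc <- sense_codons()
  nsf <- length(cfg$subfamily_sizes)
  n_per <- cfg$subfamily_sizes
  core_start <- 20L  # 0-based codon offset of the domain core
  stopifnot(core_start + .core_layout()$length + 2L < cfg$seq_codons)

  # --- gene tree: subfamily subtrees hanging off a star backbone ----
  subtrees <- lapply(seq_len(nsf), function(i) {
    tr <- ape::rtree(n_per[i], tip.label = paste0("sf", i, "g", seq_len(n_per[i])))
    .scale_to_depth(tr, cfg$crown_depth)
  })

  # --- evolve codon sequences: shared root, per-subfamily model -----
  nsites <- cfg$seq_codons
  root_states <- sample.int(61L, nsites, replace = TRUE)
  tip_rows <- character(0)
  for (i in seq_len(nsf)) {
    eig <- codon_eig(build_rate_matrix(cfg$kappa, cfg$omega[i]))
    anc <- .evolve_branch(root_states, cfg$backbone_length, eig)
    tips <- .evolve_subtree(subtrees[[i]], anc, eig)
    rows <- apply(tips, 1L, function(s) paste0(sc[s], collapse = ""))
    tip_rows <- c(tip_rows, rows)
  }
  subfamily <- rep(paste0("SF", seq_len(nsf)), n_per)
  names(subfamily) <- names(tip_rows)

  # --- duplications (before core forcing; both copies get the core) -
  duplications <- data.frame(idA = character(), idB = character(),
                             mode = character(), ks = numeric(),
                             stringsAsFactors = FALSE)
  dup_of <- function(target, ks, omega) {
    eig <- codon_eig(build_rate_matrix(cfg$kappa, omega))
    t <- ks_to_branch_length(ks, cfg$kappa, omega)
    st <- match(split_codons(tip_rows[[target]]), sc)
    new <- .evolve_branch(st, t, eig)
    paste0(sc[new], collapse = "")
  }
  if (!is.na(cfg$tandem_ks)) {
    target <- names(tip_rows)[1L]
    did <- paste0(target, "td")
    tip_rows[[did]] <- dup_of(target, cfg$tandem_ks, cfg$omega[1L])
    subfamily[did] <- subfamily[[target]]
    duplications <- rbind(duplications, data.frame(
      idA = target, idB = did, mode = "tandem", ks = cfg$tandem_ks))
  }
  if (!is.na(cfg$segmental_ks)) {
    target <- names(tip_rows)[n_per[1L] + 1L]  # first gene of SF2
    did <- paste0(target, "sd")
    tip_rows[[did]] <- dup_of(target, cfg$segmental_ks, cfg$omega[2L])
    subfamily[did] <- subfamily[[target]]
    duplications <- rbind(duplications, data.frame(
      idA = target, idB = did, mode = "segmental", ks = cfg$segmental_ks))
  }

  # --- invariant domain core, start codon, trailing stop ------------
  ids <- names(tip_rows)
  cds_rows <- .force_core(unlist(tip_rows), core_start)
  names(cds_rows) <- ids
  proteins <- vapply(cds_rows, translate_cds, character(1))
  cds_rows <- paste0(cds_rows, "TAA")
  names(cds_rows) <- ids

  species <- rep(cfg$species, length.out = length(ids))
  names(species) <- ids
  # duplicates live in the species of their template
  for (r in seq_len(nrow(duplications)))
    species[duplications$idB[r]] <- species[duplications$idA[r]]

  prot_df <- data.frame(id = ids, locus_id = ids, species = species[ids],
                        sequence = unname(proteins[ids]),
                        stringsAsFactors = FALSE)
  cds_df <- data.frame(id = ids, sequence = unname(cds_rows[ids]),
                       stringsAsFactors = FALSE)

  # --- decoys -------------------------------------------------------
  decoys <- data.frame(id = character(), type = character(),
                       stringsAsFactors = FALSE)
  if (cfg$n_incomplete > 0L) for (k in seq_len(cfg$n_incomplete)) {
    src <- ids[k]
    did <- paste0("decoyIncomplete", k)
    cds <- cds_df$sequence[match(src, cds_df$id)]
    wpos <- (core_start + .core_layout()$W) * 3L + 1L
    substr(cds, wpos, wpos + 2L) <- "TTT"  # W -> F: domain incomplete
    prot_df <- rbind(prot_df, data.frame(
      id = did, locus_id = did, species = cfg$species[1L],
      sequence = translate_cds(substr(cds, 1L, nchar(cds) - 3L))))
    cds_df <- rbind(cds_df, data.frame(id = did, sequence = cds))
    decoys <- rbind(decoys, data.frame(id = did, type = "incomplete_domain"))
  }
  if (cfg$n_extra_isoforms > 0L) for (k in seq_len(cfg$n_extra_isoforms)) {
    src <- ids[k]
    did <- paste0(src, ".iso2")
    cds <- cds_df$sequence[match(src, cds_df$id)]
    short <- paste0("ATG", substr(cds, 3L * 10L + 4L, nchar(cds)))
    prot_df <- rbind(prot_df, data.frame(
      id = did, locus_id = src, species = species[src],
      sequence = translate_cds(substr(short, 1L, nchar(short) - 3L))))
    cds_df <- rbind(cds_df, data.frame(id = did, sequence = short))
    decoys <- rbind(decoys, data.frame(id = did, type = "extra_isoform"))
  }
  if (cfg$n_pseudogenes > 0L) for (k in seq_len(cfg$n_pseudogenes)) {
    src <- ids[k + 2L]
    did <- paste0("decoyPseudo", k)
    cds <- cds_df$sequence[match(src, cds_df$id)]
    substr(cds, 3L * 10L + 1L, 3L * 10L + 3L) <- "TAA"  # internal stop
    prot_df <- rbind(prot_df, data.frame(
      id = did, locus_id = did, species = species[src],
      sequence = prot_df$sequence[match(src, prot_df$id)]))
    cds_df <- rbind(cds_df, data.frame(id = did, sequence = cds))
    decoys <- rbind(decoys, data.frame(id = did, type = "pseudogene"))
  }

  # --- promoters with planted elements ------------------------------
  planted <- list()
  promoters <- character(length(ids)); names(promoters) <- ids
  pat_max <- max(nchar(cfg$planted_elements$pattern))
  for (g in ids) {
    prom <- .random_dna(cfg$window, cfg$promoter_alphabet, cfg$background_gc)
    used <- integer(0)
    for (r in seq_len(nrow(cfg$planted_elements))) {
      pat <- cfg$planted_elements$pattern[r]
      m <- nchar(pat)
      for (cp in seq_len(cfg$planted_elements$copies[r])) {
        repeat {
          pos <- sample.int(cfg$window - m + 1L, 1L)
          if (!any(abs(pos - used) < pat_max + 1L)) break
        }
        used <- c(used, pos)
        substr(prom, pos, pos + m - 1L) <- pat
        planted[[length(planted) + 1L]] <- data.frame(
          gene = g, element = cfg$planted_elements$name[r], position = pos,
          stringsAsFactors = FALSE)
      }
    }
    promoters[g] <- prom
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene = character(), element = character(), position = integer())

  # --- genome layout and gene models --------------------------------
  genes <- list(); chrom_seq <- list(); exon_map <- list()
  exon_profile <- rep(c(2L, 2L, 1L, 3L), length.out = length(ids))
  names(exon_profile) <- ids
  intron_len <- 200L
  for (sp in cfg$species) {
    chr <- paste0("chr_", sp)
    cursor <- 0L; seqparts <- character(0)
    add_filler <- function(n = 1L) {
      for (q in seq_len(n)) {
        fid <- paste0("filler_", sp, "_", length(genes) + 1L)
        genes[[length(genes) + 1L]] <<- data.frame(
          id = fid, chromosome = chr, start = cursor + 1L,
          end = cursor + 300L, strand = "+", family = FALSE,
          stringsAsFactors = FALSE)
        exon_map[[fid]] <<- cbind(start = cursor + 1L, end = cursor + 300L)
        seqparts[length(seqparts) + 1L] <<- .random_dna(300L, gc = cfg$background_gc)
        cursor <<- cursor + 300L
      }
    }
    add_family_gene <- function(g) {
      cds <- cds_df$sequence[match(g, cds_df$id)]
      nex <- exon_profile[[g]]
      ncod <- nchar(cds) %/% 3L
      cuts <- switch(nex, integer(0),                       # 1 exon
                     (ncod %/% 2L) * 3L,                    # 2 exons
                     c((ncod %/% 3L) * 3L, (2L * ncod %/% 3L) * 3L))
      bounds <- c(0L, cuts, nchar(cds))
      segs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
      body <- paste0(segs, collapse = "")
      if (length(segs) > 1L)
        body <- paste0(segs, c(replicate(length(segs) - 1L,
                 .random_dna(intron_len, gc = cfg$background_gc)), ""),
                 collapse = "")
      seqparts[length(seqparts) + 1L] <<- promoters[[g]]
      cursor <<- cursor + nchar(promoters[[g]])
      rel_start <- cumsum(c(0L, utils::head(nchar(segs), -1L) + intron_len)) + 1L
      exon_map[[g]] <<- cbind(start = cursor + rel_start,
                              end = cursor + rel_start + nchar(segs) - 1L)
      genes[[length(genes) + 1L]] <<- data.frame(
        id = g, chromosome = chr, start = cursor + 1L,
        end = cursor + nchar(body), strand = "+", family = TRUE,
        stringsAsFactors = FALSE)
      seqparts[length(seqparts) + 1L] <<- body
      cursor <<- cursor + nchar(body)
      add_filler(1L)
    }
    sp_genes <- ids[species[ids] == sp]
    dup_ids <- duplications$idB
    tandem_partner <- if (nrow(duplications)) {
      stats::setNames(duplications$idB, duplications$idA)[duplications$mode == "tandem"]
    } else character(0)
    placed <- character(0)
    for (g in sp_genes) {
      if (g %in% placed || g %in% dup_ids) next
      add_filler(12L)
      add_family_gene(g)
      if (g %in% names(tandem_partner)) {
        add_filler(cfg$tandem_intervening - 1L)  # + the post-gene filler
        add_family_gene(tandem_partner[[g]])
        placed <- c(placed, tandem_partner[[g]])
      }
      placed <- c(placed, g)
    }
    # segmental duplicates go on a second chromosome of their species
    seg_ids <- intersect(duplications$idB[duplications$mode == "segmental"], sp_genes)
    chrom_seq[[chr]] <- paste0(seqparts, collapse = "")
    if (length(seg_ids)) {
      chr <- paste0(chr, "_seg")
      cursor <- 0L; seqparts <- character(0)
      add_filler(12L)
      for (g in seg_ids) { add_family_gene(g); placed <- c(placed, g) }
      chrom_seq[[chr]] <- paste0(seqparts, collapse = "")
    }
  }
  gene_df <- do.call(rbind, genes)
  rownames(gene_df) <- NULL
  gene_df$exons <- exon_map[gene_df$id]

  # --- anchors ------------------------------------------------------
  anchors <- data.frame(block_id = character(), geneA = character(),
                        geneB = character(), ks = numeric(),
                        stringsAsFactors = FALSE)
  seg <- duplications[duplications$mode == "segmental", , drop = FALSE]
  if (nrow(seg)) {
    for (r in seq_len(nrow(seg))) {
      blk <- paste0("block", r)
      ksv <- pmax(stats::rnorm(cfg$n_anchors, seg$ks[r], cfg$anchor_ks_sd), 0.01)
      anchors <- rbind(anchors, data.frame(
        block_id = blk,
        geneA = c(seg$idA[r], paste0("anchA", r, "_", seq_len(cfg$n_anchors - 1L))),
        geneB = c(seg$idB[r], paste0("anchB", r, "_", seq_len(cfg$n_anchors - 1L))),
        ks = ksv))
    }
    # a block killed by the Ks filter and one with too few anchors
    anchors <- rbind(anchors,
      data.frame(block_id = "blockSaturated",
                 geneA = paste0("satA", 1:4), geneB = paste0("satB", 1:4),
                 ks = stats::runif(4, 1.2, 2.5)),
      data.frame(block_id = "blockSparse",
                 geneA = paste0("spA", 1:2), geneB = paste0("spB", 1:2),
                 ks = stats::runif(2, 0.2, 0.6)))
  }

  # --- truth --------------------------------------------------------
  lam <- cfg$clock_rates[species[duplications$idA]]
  truth <- list(
    members = ids,
    subfamily = data.frame(id = ids, subfamily = unname(subfamily[ids]),
                           stringsAsFactors = FALSE),
    duplications = cbind(duplications,
                         age_mya = if (nrow(duplications))
                           duplications$ks / (2 * unname(lam)) / 1e6 else numeric(0)),
    planted_elements = planted,
    decoys = decoys,
    omega = stats::setNames(cfg$omega, paste0("SF", seq_len(nsf)))
  )

  aln <- as_aa_alignment(stats::setNames(prot_df$sequence[match(ids, prot_df$id)], ids))
  structure(list(
    config = cfg,
    proteins = prot_df,
    cds = cds_df,
    alignment = aln,
    genes = gene_df,
    genome = Biostrings::DNAStringSet(unlist(chrom_seq)),
    promoters = promoters,
    anchors = anchors,
    clock_rates = cfg$clock_rates,
    truth = truth), class = "sim_family")
}

#' Write a simulated family to disk in standard formats
#'
#' FASTA (proteins, CDS, alignment, genome), GFF3 gene models, anchor
#' TSV and truth tables.
#'
#' @param sim \code{sim_family}.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_sim_family <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) Biostrings::writeXStringSet(x, file.path(dir, f))
  w(Biostrings::AAStringSet(stats::setNames(sim$proteins$sequence, sim$proteins$id)),
    "proteins.fasta")
  w(Biostrings::DNAStringSet(stats::setNames(sim$cds$sequence, sim$cds$id)),
    "cds.fasta")
  w(Biostrings::AAStringSet(unclass(sim$alignment)), "alignment.fasta")
  w(sim$genome, "genome.fasta")
  utils::write.table(sim$anchors, file.path(dir, "anchors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gff <- sim$genes
  gr_gene <- GenomicRanges::GRanges(
    seqnames = gff$chromosome,
    ranges = IRanges::IRanges(gff$start, gff$end),
    strand = gff$strand, type = "gene", ID = gff$id)
  ex <- do.call(rbind, lapply(seq_len(nrow(gff)), function(r)
    data.frame(chromosome = gff$chromosome[r], start = gff$exons[[r]][, 1],
               end = gff$exons[[r]][, 2], strand = gff$strand[r],
               parent = gff$id[r])))
  gr_exon <- GenomicRanges::GRanges(
    seqnames = ex$chromosome, ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand, type = "exon",
    ID = paste0(ex$parent, ".exon", seq_len(nrow(ex))))
  S4Vectors::mcols(gr_exon)$Parent <- as.character(ex$parent)
  gr <- c(gr_gene, gr_exon)
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "gff3")
  utils::write.table(sim$truth$subfamily, file.path(dir, "truth_subfamily.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$duplications, file.path(dir, "truth_duplications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$planted_elements, file.path(dir, "truth_elements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Compare pipeline outputs against the planted truth
#'
#' @param sim \code{sim_family}.
#' @param catalog \code{burp_catalog} from \code{\link{build_catalog}}.
#' @param assignment Optional subfamily assignment data.frame.
#' @param tandem,segmental Optional duplication pair tables.
#' @param hits Optional promoter hit table.
#' @return data.frame with one row per compared stage: stage,
#'   precision, recall, n_truth, n_called.
#' @export
plant_truth_check <- function(sim, catalog, assignment = NULL,
                              tandem = NULL, segmental = NULL, hits = NULL) {
  pr <- function(called, truth) {
    tp <- length(intersect(called, truth))
    data.frame(precision = if (length(called)) tp / length(called) else NA,
               recall = if (length(truth)) tp / length(truth) else NA,
               n_truth = length(truth), n_called = length(called))
  }
  rows <- list()
  rows$members <- cbind(stage = "family_members",
                        pr(catalog$table$id, sim$truth$members))
  if (!is.null(assignment)) {
    tr <- sim$truth$subfamily
    m <- merge(assignment, tr, by = "id", suffixes = c("_called", "_true"))
    # labels are arbitrary; score agreement of the induced partition
    agree <- mean(vapply(seq_len(nrow(m)), function(i) {
      same_called <- m$subfamily_called == m$subfamily_called[i]
      same_true <- m$subfamily_true == m$subfamily_true[i]
      mean(same_called == same_true)
    }, numeric(1)))
    rows$subfamily <- data.frame(stage = "subfamily_partition",
                                 precision = agree, recall = agree,
                                 n_truth = nrow(tr), n_called = nrow(assignment))
  }
  key <- function(df) if (nrow(df)) paste(pmin(df$idA, df$idB),
                                          pmax(df$idA, df$idB)) else character(0)
  truthdup <- sim$truth$duplications
  if (!is.null(tandem))
    rows$tandem <- cbind(stage = "tandem_pairs",
      pr(key(tandem), key(truthdup[truthdup$mode == "tandem", ])))
  if (!is.null(segmental))
    rows$segmental <- cbind(stage = "segmental_pairs",
      pr(key(segmental), key(truthdup[truthdup$mode == "segmental", ])))
  if (!is.null(hits)) {
    hk <- paste(hits$gene, hits$element, hits$position)
    tk <- paste(sim$truth$planted_elements$gene,
                sim$truth$planted_elements$element,
                sim$truth$planted_elements$position)
    rows$elements <- cbind(stage = "planted_elements", pr(hk, tk))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
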