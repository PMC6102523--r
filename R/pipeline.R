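# Pipeline orchestration and the offline acceptance checks built on
# transcriptions of the published summary tables.

#' Path to a packaged fixture file
#'
#' @param name File name under \code{inst/extdata}.
#' @return Absolute path.
#' @export
burp_fixture <- function(name) {
  p <- system.file("extdata", name, package = "burpevol")
  if (!nzchar(p)) stop("no such fixture: ", name)
  p
}

#' Recompute the published duplication-dating and model-test numbers
#'
#' Recomputes, from the packaged table transcriptions: the
#' molecular-clock ages of the segmental pairs (T = Ks/2*lambda with
#' the species clock rates), the pair/gene bookkeeping counts (number
#' of segmental pairs, distinct segmental genes, tandem pairs with
#' 4DTv < 0.1), and the M0-vs-M3 likelihood-ratio statistic from the
#' printed log-likelihoods.
#'
#' @return List with elements \code{segmental} (dated table),
#'   \code{counts}, \code{lrt_m0_m3}, and \code{checks}
#'   (data.frame check/value/expected/pass comparing recomputed ages
#'   against the printed ones).
#' @export
acceptance_report <- function() {
  tab2 <- utils::read.delim(burp_fixture("table2_segmental.tsv"),
                            stringsAsFactors = FALSE)
  tab3 <- utils::read.delim(burp_fixture("table3_tandem.tsv"),
                            stringsAsFactors = FALSE)
  tab5 <- utils::read.delim(burp_fixture("table5_site_models.tsv"),
                            stringsAsFactors = FALSE)
  dated <- date_segmental_pairs(tab2, default_clock_rates())
  counts <- list(
    segmental_pairs = nrow(tab2),
    segmental_genes = length(unique(c(tab2$geneA, tab2$geneB))),
    tandem_pairs = nrow(tab3),
    tandem_low_4dtv = sum(tab3$d4dtv < 0.1),
    tandem_saturated = sum(tab3$d4dtv > 1)
  )
  l <- stats::setNames(tab5$lnL, tab5$model)
  lr <- lrt(l[["M3"]], l[["M0"]], df = 4L)
  checks <- data.frame(
    check = paste0("age_", dated$geneA, "_", dated$geneB),
    value = dated$age_mya,
    expected = dated$age_printed_mya,
    pass = dated$age_mya == dated$age_printed_mya)
  checks <- rbind(checks, data.frame(
    check = c("segmental_pairs", "segmental_genes", "tandem_low_4dtv",
              "lrt_m0_m3"),
    value = c(counts$segmental_pairs, counts$segmental_genes,
              counts$tandem_low_4dtv, lr$stat),
    expected = c(10, 16, 17, 1029.4),
    pass = c(counts$segmental_pairs == 10, counts$segmental_genes == 16,
             counts$tandem_low_4dtv == 17, abs(lr$stat - 1029.4) < 1e-6)))
  list(segmental = dated, counts = counts, lrt_m0_m3 = lr, checks = checks)
}

#' Run the full analysis pipeline on a simulated family
#'
#' Orchestrates catalog curation, NJ tree with bootstrap, subfamily
#' assignment, codon back-translation, tandem/segmental duplication
#' calls with 4DTv and clock dating, promoter element scanning, and
#' the truth comparison. Selection-model and divergence fits are
#' compute-heavy and exposed through their own functions rather than
#' this driver.
#'
#' @param sim A \code{sim_family} from \code{\link{simulate_family}}.
#' @param outdir Optional directory: all tables are written as TSV,
#'   the tree as Newick, plus a small run log.
#' @param n_boot Bootstrap replicates for the tree (default 100).
#' @param seed Seed for the bootstrap resampling.
#' @param seeds Subfamily seed list (label -> tip ids); by default the
#'   two first true members of each simulated subfamily.
#' @param max_intervening,ks_max,min_anchors Duplication thresholds.
#' @param elements Element definition table; defaults to the planted
#'   element set of the simulation.
#' @return List of stage outputs (catalog, tree, assignment, pairs,
#'   dated segmental table, promoter hits and summary, truth report).
#' @export
run_pipeline <- function(sim, outdir = NULL, n_boot = 100L, seed = 1L,
                         seeds = NULL, max_intervening = 10L, ks_max = 1.0,
                         min_anchors = 3L, elements = NULL) {
  stopifnot(inherits(sim, "sim_family"))
  catalog <- build_catalog(sim$proteins, sim$cds)
  fam_ids <- catalog$table$id

  aln <- as_aa_alignment(unclass(sim$alignment)[fam_ids])
  tree <- bootstrap_support(aln, n_reps = n_boot, seed = seed)
  if (is.null(seeds)) {
    tr <- sim$truth$subfamily
    seeds <- lapply(split(tr$id, tr$subfamily), function(x)
      intersect(x, fam_ids)[1:2])
  }
  assignment <- assign_subfamilies(tree, seeds)

  caln <- back_translate(aln, catalog$cds)
  tandem <- tandem_pairs(sim$genes, fam_ids, max_intervening)
  if (nrow(tandem)) {
    tandem$d4dtv <- vapply(seq_len(nrow(tandem)), function(r)
      d4dtv(unclass(caln)[[tandem$idA[r]]], unclass(caln)[[tandem$idB[r]]])$d4dtv,
      numeric(1))
    tandem$ks <- vapply(seq_len(nrow(tandem)), function(r)
      ng86_rates(unclass(caln)[[tandem$idA[r]]], unclass(caln)[[tandem$idB[r]]])$Ks,
      numeric(1))
  }
  segmental <- segmental_pairs(sim$anchors, fam_ids, ks_max, min_anchors)
  if (nrow(segmental)) {
    segmental$species <- sim$proteins$species[match(segmental$idA, sim$proteins$id)]
    segmental <- date_segmental_pairs(segmental, sim$clock_rates)
  }
  if (is.null(elements)) {
    pe <- sim$config$planted_elements
    elements <- data.frame(name = pe$name, pattern = pe$pattern,
                           category = "planted", stringsAsFactors = FALSE)
  }
  hits <- scan_promoters(sim$promoters[fam_ids], elements)
  summary <- summarize_elements(hits, assignment)
  truth_report <- plant_truth_check(sim, catalog, assignment,
                                    tandem, segmental,
                                    hits[hits$strand == "+", , drop = FALSE])
  out <- list(catalog = catalog, tree = tree, assignment = assignment,
              codon_alignment = caln, tandem = tandem,
              segmental = segmental, hits = hits,
              element_summary = summary, truth_report = truth_report,
              thresholds = list(max_intervening = max_intervening,
                                ks_max = ks_max, min_anchors = min_anchors,
                                n_boot = n_boot, seed = seed))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_catalog(catalog, outdir)
    write_support_tree(tree, file.path(outdir, "nj_tree.nwk"))
    wt <- function(df, f) utils::write.table(df, file.path(outdir, f),
      sep = "\t", quote = FALSE, row.names = FALSE)
    wt(assignment, "subfamilies.tsv")
    wt(tandem, "tandem_pairs.tsv")
    wt(segmental[, setdiff(names(segmental), "exons")], "segmental_pairs.tsv")
    wt(hits, "promoter_hits.tsv")
    wt(truth_report, "truth_report.tsv")
    log <- c(paste("burpevol", as.character(utils::packageVersion("burpevol"))),
             paste("seed", seed),
             paste("thresholds: max_intervening", max_intervening,
                   "ks_max", ks_max, "min_anchors", min_anchors,
                   "n_boot", n_boot))
    writeLines(log, file.path(outdir, "run_log.txt"))
  }
  out
}
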