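mk_genes <- function(n, chr = "c1", fam = integer(0)) {
  data.frame(id = sprintf("g%02d", seq_len(n)), chromosome = chr,
             start = seq_len(n) * 1000L, stringsAsFactors = FALSE)
}

test_that("tandem calls respect the intervening-gene bound inclusively", {
  g <- mk_genes(30)
  # ranks 5 and 7: one intervening gene
  p <- tandem_pairs(g, c("g05", "g07"))
  expect_equal(nrow(p), 1L)
  expect_equal(p$intervening, 1L)
  # boundary: ranks 5 and 16 -> 10 intervening (kept), 5 and 17 -> 11 (dropped)
  expect_equal(nrow(tandem_pairs(g, c("g05", "g16"))), 1L)
  expect_equal(tandem_pairs(g, c("g05", "g16"))$intervening, 10L)
  expect_equal(nrow(tandem_pairs(g, c("g05", "g17"))), 0L)
  # different chromosomes never pair
  g2 <- rbind(g, within(mk_genes(5, chr = "c2"), id <- paste0(id, "b")))
  expect_equal(nrow(tandem_pairs(g2, c("g05", "g01b"))), 0L)
  expect_error(tandem_pairs(g, "missing"), "missing from annotation")
})

test_that("tandem calls are invariant to record shuffling and pair order", {
  g <- mk_genes(25)
  fam <- c("g03", "g05", "g20")
  base <- tandem_pairs(g, fam)
  set.seed(2)
  for (i in 1:5) {
    shuf <- g[sample(nrow(g)), ]
    expect_equal(tandem_pairs(shuf, fam), base)
    expect_equal(tandem_pairs(shuf, rev(fam)), base)
  }
})

test_that("segmental blocks are filtered on Ks and anchor count", {
  anch <- data.frame(
    block_id = c(rep("b1", 3), rep("b2", 3)),
    geneA = c("f1", "x1", "x2", "f3", "y1", "y2"),
    geneB = c("f2", "x3", "x4", "f4", "y3", "y4"),
    ks = c(0.4, 0.5, 0.6, 0.4, 1.2, 0.5), stringsAsFactors = FALSE)
  fam <- c("f1", "f2", "f3", "f4")
  out <- segmental_pairs(anch, fam)
  # b1 kept with mean 0.5; b2 loses an anchor to the Ks filter and dies
  expect_equal(nrow(out), 1L)
  expect_equal(out$ks_mean, 0.5)
  expect_equal(sort(c(out$idA, out$idB)), c("f1", "f2"))
  # lowering min_anchors revives b2
  out2 <- segmental_pairs(anch, fam, min_anchors = 2L)
  expect_equal(nrow(out2), 2L)
})

test_that("anchor files are parsed strictly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("block_id\tgeneA\tgeneB\tks", "b1\ta\tb\t0.5", "b1\tc\td"), f)
  expect_error(read_anchors(f), "line 3")
  writeLines(c("b1\ta\tb\t0.5", "b1\tc\td\tx"), f)
  expect_error(read_anchors(f), "line 2")
  writeLines(c("block_id\tgeneA\tgeneB\tks", "b1\ta\tb\t0.5"), f)
  expect_equal(read_anchors(f)$ks, 0.5)
})

test_that("molecular-clock dating reproduces the published ages", {
  expect_equal(date_pair(0.795, 1.5e-8)$age_mya, 26.5)
  expect_equal(date_pair(0.553, 6.1e-9)$age_mya, 45.3)
  expect_equal(date_pair(0, 1e-8)$age_mya, 0)
  # linear in Ks, inverse-linear in lambda (raw values)
  expect_equal(date_pair(0.4, 1e-8)$age_mya_raw,
               2 * date_pair(0.2, 1e-8)$age_mya_raw)
  expect_equal(date_pair(0.4, 2e-8)$age_mya_raw,
               date_pair(0.2, 1e-8)$age_mya_raw)
  expect_error(date_pair(0.4, 0))
})

test_that("exon counting works directly and through a GFF round trip", {
  g <- list(exons = cbind(start = c(1, 100), end = c(50, 200)))
  expect_equal(exon_count(g), 2L)
  expect_equal(exon_count(list(exons = cbind(start = 1, end = 9))), 1L)
  expect_error(exon_count(list(exons = NULL)), "no annotated exons")
  # 18-exon gene written as GFF3 and read back
  dir <- withr::local_tempdir()
  starts <- seq(1, by = 100, length.out = 18)
  gr <- c(
    GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 1800), "+",
                           type = "gene", ID = "big"),
    GenomicRanges::GRanges("chrT", IRanges::IRanges(starts, starts + 49), "+",
                           type = "exon", ID = paste0("big.e", 1:18)))
  S4Vectors::mcols(gr)$Parent <- c(NA, rep("big", 18))
  f <- file.path(dir, "t.gff3")
  rtracklayer::export(gr, f, format = "gff3")
  gm <- read_gene_models(f)
  expect_equal(exon_count(gm[gm$id == "big", ]), 18L)
})

test_that("dating a table attaches ages using per-species clocks", {
  tab <- data.frame(idA = "a", idB = "b", ks_mean = 0.795,
                    species = "arabidopsis")
  out <- date_segmental_pairs(tab)
  expect_equal(out$age_mya, 26.5)
  expect_error(date_segmental_pairs(
    data.frame(ks_mean = 1, species = "unknown")), "no clock rate")
})
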