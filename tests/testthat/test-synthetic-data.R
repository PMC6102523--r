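test_that("the generator is deterministic for a fixed seed", {
  s1 <- simulate_family(sim_config(seed = 4))
  s2 <- simulate_family(sim_config(seed = 4))
  expect_identical(s1$proteins, s2$proteins)
  expect_identical(s1$cds, s2$cds)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$anchors, s2$anchors)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_family(sim_config(seed = 5))
  expect_false(identical(s1$proteins, s3$proteins))
})

test_that("every non-decoy protein carries the invariant domain core", {
  sim <- simulate_family(sim_config(seed = 7))
  for (id in sim$truth$members) {
    h <- scan_burp_domain(sim$proteins$sequence[match(id, sim$proteins$id)])
    expect_false(is.null(h))
    expect_true(h$complete)
  }
})

test_that("a zero-depth duplication yields identical partners", {
  sim <- simulate_family(sim_config(seed = 9, tandem_ks = 0))
  dup <- sim$truth$duplications
  td <- dup[dup$mode == "tandem", ]
  caln <- back_translate(sim$alignment, sim$cds)
  a <- unclass(caln)[[td$idA]]; b <- unclass(caln)[[td$idB]]
  expect_identical(a, b)
  expect_equal(d4dtv(a, b)$d4dtv, 0)
  expect_equal(ng86_rates(a, b)$Ks, 0)
})

test_that("branch calibration puts realized NG86 Ks near the target depth", {
  set.seed(60)
  sc <- burpevol:::sense_codons()
  for (depth in c(0.2, 0.5, 0.8)) {
    t <- ks_to_branch_length(depth, kappa = 2, omega = 0.2)
    eig <- burpevol:::codon_eig(build_rate_matrix(2, 0.2))
    root <- sample.int(61, 1000, replace = TRUE)
    child <- burpevol:::.evolve_branch(root, t, eig)
    ks <- ng86_rates(paste0(sc[root], collapse = ""),
                     paste0(sc[child], collapse = ""))$Ks
    expect_equal(ks, depth, tolerance = 0.15)
  }
})

test_that("planted promoter elements are exactly recovered on a clean background", {
  cfg <- sim_config(seed = 21, promoter_alphabet = c("A", "T"),
                    subfamily_sizes = c(3L, 3L))
  sim <- simulate_family(cfg)
  defs <- data.frame(name = cfg$planted_elements$name,
                     pattern = cfg$planted_elements$pattern,
                     category = "planted")
  hits <- scan_promoters(sim$promoters, defs, both_strands = FALSE)
  key <- function(d) sort(paste(d$gene, d$element, d$position))
  expect_identical(key(hits),
                   key(stats::setNames(sim$truth$planted_elements,
                                       c("gene", "element", "position"))))
})

test_that("gene layout reproduces the configured tandem separation", {
  cfg <- sim_config(seed = 31, tandem_intervening = 3L)
  sim <- simulate_family(cfg)
  td <- sim$truth$duplications[sim$truth$duplications$mode == "tandem", ]
  pairs <- tandem_pairs(sim$genes, sim$truth$members)
  hit <- pairs[pairs$idA %in% c(td$idA, td$idB) &
               pairs$idB %in% c(td$idA, td$idB), ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$intervening, 3L)
  # pushed past the bound, the pair is no longer called
  sim11 <- simulate_family(sim_config(seed = 31, tandem_intervening = 11L))
  td11 <- sim11$truth$duplications[sim11$truth$duplications$mode == "tandem", ]
  pairs11 <- tandem_pairs(sim11$genes, sim11$truth$members)
  expect_equal(nrow(pairs11[pairs11$idA %in% c(td11$idA, td11$idB) &
                            pairs11$idB %in% c(td11$idA, td11$idB), ]), 0L)
})

test_that("written outputs round-trip through the standard parsers", {
  sim <- simulate_family(sim_config(seed = 41, subfamily_sizes = c(3L, 3L)))
  dir <- withr::local_tempdir()
  write_sim_family(sim, dir)
  prot <- read_fasta_df(file.path(dir, "proteins.fasta"), "protein")
  expect_setequal(prot$id, sim$proteins$id)
  anch <- read_anchors(file.path(dir, "anchors.tsv"))
  expect_equal(nrow(anch), nrow(sim$anchors))
  gm <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_setequal(gm$id, sim$genes$id)
  fam <- intersect(gm$id, sim$truth$members)
  for (g in fam) {
    expect_equal(exon_count(gm[gm$id == g, ]),
                 nrow(sim$genes$exons[[match(g, sim$genes$id)]]))
  }
  # genome FASTA agrees with coordinates: re-extract a promoter
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fasta"))
  g1 <- sim$genes[sim$genes$id == fam[1], ]
  up <- extract_upstream(genome, g1, window = sim$config$window)
  expect_equal(unname(as.character(up)), unname(sim$promoters[fam[1]]))
})
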