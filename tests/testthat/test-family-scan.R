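make_burp <- function(s1 = 10, s2 = 25, s3 = 24, s4 = 8, tail = "W",
                      pad_left = "", pad_right = "") {
  paste0(pad_left, "CH", strrep("A", s1), "CH", strrep("A", s2),
         "CH", strrep("A", s3), "CH", strrep("A", s4), tail, pad_right)
}

test_that("domain scanner finds the canonical pattern and respects anchors", {
  h <- scan_burp_domain(make_burp())
  expect_equal(h$start, 1L)
  expect_true(h$complete)
  expect_equal(h$motif_spans$label[1:5], c("CH1", "CH2", "CH3", "CH4", "W"))
  # terminal W is required
  expect_null(scan_burp_domain(make_burp(tail = "F")))
  # spacer below the admissible range between dyads 2-3
  expect_null(scan_burp_domain(make_burp(s2 = 22)))
  expect_null(scan_burp_domain(make_burp(s3 = 27)))
  # spacer range boundaries are admissible
  expect_true(scan_burp_domain(make_burp(s2 = 23))$complete)
  expect_true(scan_burp_domain(make_burp(s2 = 27, s3 = 23))$complete)
  # leftmost match is reported
  h2 <- scan_burp_domain(make_burp(pad_left = strrep("G", 7),
                                   pad_right = make_burp()))
  expect_equal(h2$start, 8L)
  # X may fill spacers but not anchors
  xs <- make_burp(); substr(xs, 3, 3) <- "X"
  expect_true(scan_burp_domain(xs)$complete)
  ws <- make_burp(); substr(ws, 1, 1) <- "X"
  expect_null(scan_burp_domain(ws))
  expect_error(scan_burp_domain("CHB*"), "invalid residue")
})

test_that("domain scanner agrees with the spacer-enumeration oracle", {
  set.seed(42)
  # enriched alphabet so matches actually occur at a useful rate
  pr <- stats::setNames(rep(0.3 / 17, 20), AA20)
  pr[c("C", "H")] <- 0.3; pr["W"] <- 0.1
  n_match <- 0L
  for (i in 1:200) {
    s <- paste0(sample(AA20, 500, replace = TRUE, prob = pr), collapse = "")
    got <- scan_burp_domain(s)
    want <- oracle_burp_scan(s)
    expect_equal(is.null(got), is.null(want), info = paste("string", i))
    if (!is.null(got)) {
      n_match <- n_match + 1L
      expect_equal(got$start, want$start, info = paste("string", i))
      expect_equal(got$end, want$end, info = paste("string", i))
    }
  }
  expect_gt(n_match, 5L)
})

test_that("longest isoform is kept per locus with deterministic ties", {
  rec <- data.frame(
    id = c("g1.2", "g1.1", "g2.1", "g3.b", "g3.a"),
    locus_id = c("g1", "g1", "g2", "g3", "g3"),
    sequence = c(strrep("A", 300), strrep("A", 250), "MKV",
                 strrep("C", 80), strrep("D", 80)),
    stringsAsFactors = FALSE)
  out <- select_longest_isoform(rec)
  expect_equal(sort(out$id), c("g1.2", "g2.1", "g3.a"))
  expect_equal(nrow(out), length(unique(rec$locus_id)))
})

test_that("complete-ORF test checks start, stop, frame and case", {
  expect_true(as.logical(check_complete_orf("ATGGGATAA")))
  expect_false(as.logical(check_complete_orf("ATGGGATAAGGA")))
  expect_false(as.logical(check_complete_orf("ATGGGATA")))
  expect_false(as.logical(check_complete_orf("TTGGGATAA")))
  # case invariance
  for (s in c("ATGGGATAA", "ATGGGATAAGGA", "atgCCCtgGtaG")) {
    expect_identical(as.logical(check_complete_orf(tolower(s))),
                     as.logical(check_complete_orf(toupper(s))))
  }
  # N codons are non-stop but flagged
  r <- check_complete_orf("ATGNNNTAA")
  expect_true(as.logical(r))
  expect_true(attr(r, "ambiguous"))
  expect_error(check_complete_orf("ATGZZZTAA"), "invalid nucleotide")
})

test_that("catalog curation excludes decoys and reports them", {
  sim <- simulate_family(sim_config(seed = 11))
  cat <- build_catalog(sim$proteins, sim$cds)
  expect_setequal(cat$table$id, sim$truth$members)
  # each decoy excluded for its planted reason
  dec <- merge(sim$truth$decoys, cat$excluded, by = "id")
  expect_equal(nrow(dec), nrow(sim$truth$decoys))
  expect_true(all(dec$reason[dec$type == "incomplete_domain"] == "incomplete_domain"))
  expect_true(all(dec$reason[dec$type == "pseudogene"] == "incomplete_orf"))
  expect_true(all(dec$reason[dec$type == "extra_isoform"] == "redundant_isoform"))
  expect_error(build_catalog(sim$proteins,
                             sim$cds[-1, , drop = FALSE]), "no CDS record")
  expect_warning(out <- build_catalog(sim$proteins[0, ], sim$cds), "empty")
  expect_equal(nrow(out$table), 0L)
})
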