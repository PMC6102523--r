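test_that("upstream windows honour strand and chromosome edges", {
  chr <- paste0(strrep("A", 500), strrep("C", 1500), strrep("G", 300))
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  plus <- extract_upstream(genome,
    list(chromosome = "chr1", start = 2001, end = 2200, strand = "+"),
    window = 1500)
  expect_equal(nchar(plus), 1500)
  expect_equal(unname(as.character(plus)), strrep("C", 1500))
  expect_false(attr(plus, "truncated"))
  # minus strand: reverse complement downstream-of-end window
  minus <- extract_upstream(genome,
    list(chromosome = "chr1", start = 1, end = 500, strand = "-"),
    window = 1500)
  expect_equal(unname(as.character(minus)), strrep("G", 1500))
  # double reverse-complement is the identity
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::reverseComplement(Biostrings::DNAString(minus)))),
    unname(as.character(minus)))
  short <- extract_upstream(genome,
    list(chromosome = "chr1", start = 100, end = 150, strand = "+"),
    window = 1500)
  expect_equal(nchar(short), 99)
  expect_true(attr(short, "truncated"))
  expect_error(extract_upstream(genome,
    list(chromosome = "chrX", start = 10, end = 20, strand = "+")),
    "not in genome")
})

test_that("element scanning matches IUPAC semantics on both strands", {
  defs <- data.frame(name = "E", pattern = "ACGTG", category = "x")
  h <- scan_elements("TTACGTGGC", defs)
  expect_equal(h$position[h$strand == "+"], 3L)
  h2 <- scan_elements("TTACGTGGC", data.frame(name = "E", pattern = "CACGT",
                                              category = "x"))
  expect_equal(h2$strand, "-")
  expect_equal(h2$position, 3L)  # reverse complement ACGTG at 3
  # degenerate positions
  h3 <- scan_elements("AAACGTAAA", data.frame(name = "E", pattern = "ACGTR",
                                              category = "x"),
                      both_strands = FALSE)
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$position, 3L)
  expect_error(scan_elements("ACGT", data.frame(name = "E", pattern = "ACGJ",
                                                category = "x")),
               "invalid IUPAC")
  # overlapping matches are all reported
  h4 <- scan_elements("AAAA", data.frame(name = "E", pattern = "AA",
                                         category = "x"), both_strands = FALSE)
  expect_equal(h4$position, 1:3)
})

test_that("scanning is strand-symmetric under reverse complement", {
  set.seed(5)
  defs <- read_cis_elements(burp_fixture("cis_elements.tsv"))
  seq <- paste0(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- scan_elements(seq, defs)
  rev <- scan_elements(rc, defs)
  L <- nchar(seq)
  mirror <- function(h, defs) {
    m <- nchar(defs$pattern[match(h$element, defs$name)])
    data.frame(element = h$element,
               position = L - (h$position + m - 1L) + 1L,
               strand = ifelse(h$strand == "+", "-", "+"))
  }
  key <- function(d) sort(paste(d$element, d$position, d$strand))
  expect_equal(key(mirror(rev, defs)), key(fwd))
})

test_that("subfamily summaries add up and report count/members", {
  hits <- data.frame(gene = c("g1", "g1", "g3"),
                     element = c("MBS", "MBS", "MBS"),
                     position = c(1L, 7L, 4L), strand = "+")
  asg <- data.frame(id = c("g1", "g2", "g3"),
                    subfamily = c("A", "A", "B"))
  s <- summarize_elements(hits, asg)
  expect_equal(unname(s$display["A", "MBS"]), "2/2")
  expect_equal(unname(s$display["B", "MBS"]), "1/1")
  expect_equal(unname(s$total["MBS"]), 3L)
  expect_equal(sum(s$counts[, "MBS"]), unname(s$total["MBS"]))
  expect_equal(unname(s$mean_copies["MBS"]), 1)
  empty <- summarize_elements(hits[0, ], asg)
  expect_true(all(empty$counts == 0))
  expect_error(summarize_elements(
    data.frame(gene = "nope", element = "E", position = 1L, strand = "+"), asg),
    "without subfamily")
})
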