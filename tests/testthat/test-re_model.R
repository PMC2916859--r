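# Response-element parsing, consensus scoring and contact-partner
# resolution.

test_that("parse_re tokenizes the published sequences into quarter sites", {
  re <- parse_re("14-3-3sigma", "AGGCATGTGC CACCATGCCC")
  expect_equal(unname(re$quarter_sites),
               c("AGGCA", "TGTGC", "CACCA", "TGCCC"))
  expect_equal(re$half_sites, c("AGGCATGTGC", "CACCATGCCC"))
  expect_equal(paste(re$quarter_sites, collapse = ""), re$sequence)

  puma <- parse_re("Puma", "CTGCAAGTCC TGACTTGTCC")
  expect_equal(substr(puma$quarter_sites[["Q3"]], 1, 1), "T")
})

test_that("parse_re rejects malformed input with informative errors", {
  expect_error(parse_re("short", "AGGCATGTGCCACCATGCC"), "20 bases.*19")
  expect_error(parse_re("bad", "AGGXATGTGCCACCATGCCC"), "'X' at position 4")
})

test_that("consensus scoring flags exactly the published deviations", {
  sig <- score_consensus(parse_re("14-3-3sigma", "AGGCATGTGCCACCATGCCC"))
  expect_equal(sig$mismatch_count, 3)
  bad <- sig$report[!sig$report$match, c("quarter", "label")]
  expect_equal(paste(bad$quarter, bad$label),
               c("Q2 2'", "Q3 1", "Q3 3"))

  gadd <- score_consensus(parse_re("GADD45", "GAACATGTCTAAGCATGCTG"))
  expect_equal(gadd$mismatch_count, 1)
  expect_equal(paste(gadd$report$quarter[!gadd$report$match],
                     gadd$report$label[!gadd$report$match]), "Q4 1'")

  perfect <- score_consensus(parse_re("consensus", "AAACATGTTTAAACATGTTT"))
  expect_equal(perfect$mismatch_count, 0)
})

test_that("the six published elements deviate by one to three positions", {
  ref <- p53_response_elements()
  counts <- vapply(seq_len(nrow(ref)), function(i)
    score_consensus(parse_re(ref$name[i], ref$sequence[i]))$mismatch_count,
    integer(1))
  expect_equal(min(counts), 1)
  expect_equal(max(counts), 3)
  expect_true(all(counts >= 1 & counts <= 3))
})

test_that("reverse complement matches definition and the Biostrings oracle", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AGGCA"), "TGCCT")
  expect_error(reverse_complement("AGN"), "invalid character")
  skip_if_not_installed("Biostrings")
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
               collapse = "")
    expect_equal(reverse_complement(s),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(s))))
  }
})

test_that("half-site motif is palindromic under class mapping", {
  half <- consensus_motif(full = FALSE)
  expect_length(half, 10)
  my_mismatch <- function(s) {
    b <- strsplit(s, "")[[1]]
    sum(!mapply(base_in_class, b, as.character(half)))
  }
  set.seed(21)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
               collapse = "")
    m <- my_mismatch(s)
    expect_identical(m, oracle_half_mismatch(s))
    expect_identical(m, my_mismatch(reverse_complement(s)))
  }
})

test_that("contact_partner resolves strand and base per quarter-site label", {
  re <- parse_re("14-3-3sigma", "AGGCATGTGCCACCATGCCC")
  p <- contact_partner(re, "Q1", "2")
  expect_equal(p$strand, "reference")
  expect_equal(p$base, "G")

  p4 <- contact_partner(re, "Q2", "4'")
  expect_equal(p4$strand, "complementary")
  expect_equal(p4$base, "G")
  # the quarter-local strand shows the conserved C at the paired column
  loc <- contact_partner(re, "Q2", "4")
  expect_equal(loc$base, "C")

  expect_error(contact_partner(re, "Q1", "6"), "unknown.*label")
  # label 0: the bp 5'-adjacent to local position 1
  p0 <- contact_partner(re, "Q3", "0")
  expect_equal(p0$column, 10)
  expect_true(is.na(contact_partner(re, "Q1", "0")$base))
})
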