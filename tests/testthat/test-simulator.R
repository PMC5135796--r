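test_that("synthetic references carry exactly the catalogued tracts", {
  syn <- make_synthetic_reference(length = 30000L, n_regions = 12L, seed = 3)
  expect_equal(nrow(syn$regions), 12L)
  refseq <- syn$reference[[1]]
  for (r in seq_len(nrow(syn$regions))) {
    g <- syn$regions[r, ]
    tract <- substr(refseq, g$start + 1L, g$end)
    expect_equal(tract, strrep(g$unit, g$ref_size / g$period))
    # catalogued interval is maximal: neighbors break the repeat
    tr <- extract_maximal_repeat_region(
      substr(refseq, g$start - 4L, g$end + 5L), g$unit, 0)
    expect_equal(tr$length, g$ref_size)
  }
})

test_that("diploid genomes are deterministic and within the size cap", {
  syn <- make_synthetic_reference(length = 30000L, n_regions = 12L, seed = 3)
  g1 <- simulate_diploid_genome(syn$reference, syn$regions, seed = 9)
  g2 <- simulate_diploid_genome(syn$reference, syn$regions, seed = 9)
  expect_identical(g1$haplotypes, g2$haplotypes)
  expect_identical(g1$truth, g2$truth)
  g3 <- simulate_diploid_genome(syn$reference, syn$regions, seed = 10)
  expect_false(identical(g1$haplotypes, g3$haplotypes))
  for (s in 1:20) { # repeated draws stay within the cap
    g <- simulate_diploid_genome(syn$reference, syn$regions, seed = 100 + s)
    expect_true(all(c(g$truth$a1, g$truth$a2) <= 100))
    expect_true(all(c(g$truth$a1, g$truth$a2) >= g$truth$period))
    expect_equal(g$truth$a1, g$truth$copies1 * g$truth$period)
  }
  # haplotype tract content matches the sampled allele
  h1 <- g1$haplotypes[1]
  l1 <- g1$liftover[[1]]
  for (r in seq_len(nrow(l1))) {
    tract <- substr(h1, l1$hap_start[r] + 1L, l1$hap_end[r])
    expect_equal(tract, strrep(g1$truth$unit[r], g1$truth$copies1[r]))
  }
})

test_that("read simulation honors its error, insert and coverage settings", {
  syn <- make_synthetic_reference(length = 30000L, n_regions = 12L, seed = 3)
  g <- simulate_diploid_genome(syn$reference, syn$regions, seed = 9)
  reads <- simulate_reads(g, coverage = 40, seed = 11)
  expect_identical(reads, simulate_reads(g, coverage = 40, seed = 11))

  # empirical substitution rate vs the source haplotype, over >= 1e6 bases
  nmis <- 0L; nb <- 0L
  for (h in 1:2) {
    rr <- reads[reads$hap == h, ]
    src <- substring(g$haplotypes[h], rr$hap_pos, rr$hap_pos + 99L)
    src[rr$strand == "-"] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(src[rr$strand == "-"])))
    a <- strsplit(paste(rr$seq, collapse = ""), "")[[1]]
    b <- strsplit(paste(src, collapse = ""), "")[[1]]
    nmis <- nmis + sum(a != b); nb <- nb + length(a)
  }
  expect_gt(nb, 1e6)
  p <- nmis / nb
  expect_lt(abs(p - 0.001), 3 * sqrt(0.001 * 0.999 / nb))

  # insert size: mean within 3 sigma of 500
  m1 <- reads[reads$mate == 1L, ]; m2 <- reads[reads$mate == 2L, ]
  m2 <- m2[match(m1$qname, m2$qname), ]
  ins <- (m2$hap_pos + 100L - 1L) - m1$hap_pos + 1L
  expect_lt(abs(mean(ins) - 500), 3 * 50 / sqrt(length(ins)))

  # coverage within 5%
  cov <- nrow(reads) * 100 / nchar(syn$reference[[1]])
  expect_lt(abs(cov - 40) / 40, 0.05)

  # qualities encode Q30
  expect_true(all(reads$qual == strrep("?", 100)))
  expect_error(simulate_reads(g, insert_mean = 50, read_len = 100), "insert_mean")
})

test_that("the spanning estimator calls modes and respects min_span", {
  reg <- str_regions("chrE", 100L, 124L, 4L, "GGAT")
  mk <- function(n, cigar, pos = 81L) data.frame(
    qname = sprintf("r%02d", seq_len(n)), flag = 0L, rname = "chrE",
    pos = pos, mapq = 60L, cigar = cigar, rnext = "chrE", pnext = 0L,
    tlen = 0L, seq = strrep("A", 60), qual = strrep("?", 60), tags = "",
    stringsAsFactors = FALSE)
  # 10 spanning reads all implying 24 bp (reference size): unanimous call
  calls <- naive_spanning_estimator(mk(10, "60M"), reg)
  expect_equal(c(calls$a1, calls$a2), c(24L, 24L))
  # 5 reads implying 20 bp (4 bp deletion), 5 implying 24: two modes
  rec <- rbind(mk(5, "30M4D30M"), mk(5, "60M"))
  rec$qname <- sprintf("r%02d", 1:10)
  calls <- naive_spanning_estimator(rec, reg)
  expect_equal(c(calls$a1, calls$a2), c(20L, 24L))
  # insufficient spanning depth
  calls <- naive_spanning_estimator(mk(2, "60M"), reg, min_span = 3L)
  expect_true(is.na(calls$a1) && is.na(calls$a2))
  expect_equal(calls$n_span, 2L)
  # homozygous rule: 8 of 10 at one size
  rec <- rbind(mk(8, "30M4D30M"), mk(2, "60M"))
  rec$qname <- sprintf("r%02d", 1:10)
  calls <- naive_spanning_estimator(rec, reg)
  expect_equal(c(calls$a1, calls$a2), c(20L, 20L))
  # a read that does not span (stops inside the region) is ignored
  rec <- rbind(mk(3, "60M"), mk(3, "40M20S", pos = 70L))
  rec$qname <- sprintf("r%02d", 1:6)
  calls <- naive_spanning_estimator(rec, reg)
  expect_equal(calls$n_span, 3L)
})
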