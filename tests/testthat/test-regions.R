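test_that("str_regions validates its invariants", {
  r <- str_regions("chr1", 100L, 120L, 2L, "AC")
  expect_s3_class(r, "str_regions")
  expect_equal(r$ref_size, 20L)
  expect_error(str_regions("chr1", 100, 120, 7, "ACGTACG"), "period")
  expect_error(str_regions("chr1", 100, 120, 3, "AC"), "unit length")
  expect_error(str_regions("chr1", 100, 120, 2, "AN"), "only A/C/G/T")
  expect_error(str_regions("chr1", 120, 100, 2, "AC"), "start")
})

test_that("catalog files round-trip and reject malformed lines", {
  r <- str_regions(c("chr1", "chr2"), c(10L, 50L), c(30L, 62L),
                   c(2L, 3L), c("AC", "GAT"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_str_catalog(r, path)
  writeLines(c("# a comment", readLines(path)), path)
  r2 <- read_str_catalog(path)
  expect_equal(r2$start, r$start)
  expect_equal(r2$unit, r$unit)
  writeLines(c("chr1\t10\t30"), path)
  expect_error(read_str_catalog(path), "malformed")
})

test_that("catalog size filter keeps the 100 bp boundary inclusive", {
  r <- str_regions("chr1", c(0L, 200L, 400L), c(100L, 301L, 440L),
                   c(2L, 2L, 4L), c("AC", "AC", "ACGT"))
  f <- filter_catalog(r, 100L)
  expect_equal(f$start, c(0L, 400L)) # 101 bp region dropped
  expect_equal(nrow(filter_catalog(r[0, ], 100L)), 0L)
})

test_that("long-homopolymer screen is exact and monotone in tract size", {
  r <- str_regions("chr1", c(0L, 100L, 200L), c(16L, 114L, 240L),
                   c(1L, 1L, 2L), c("A", "T", "AC"))
  expect_equal(is_long_homopolymer(r, 15L), c(TRUE, FALSE, FALSE))
  # monotone: lengthening a screened-in homopolymer never unscreens it
  sizes <- 5:40
  rr <- str_regions("chr1", 0L, sizes, 1L, "A")
  flags <- is_long_homopolymer(rr, 15L)
  expect_true(all(diff(flags) >= 0))
  expect_equal(flags, sizes >= 15L)
})

# Brute-force reference for tract extraction: score every interval at every
# frame anchored at its start.
brute_max_tract <- function(seq, unit, error_rate) {
  L <- nchar(seq); u <- nchar(unit)
  sb <- strsplit(seq, "")[[1]]; ub <- strsplit(unit, "")[[1]]
  best <- NULL
  for (s in 1:L) for (e in s:L) {
    len <- e - s + 1L
    if (len < u) next
    mism <- sum(sb[s:e] != ub[((seq_len(len) - 1L) %% u) + 1L])
    if (mism <= error_rate * len) {
      if (is.null(best) || len > best$length) best <- list(offset = s - 1L, length = len)
    }
  }
  best
}

test_that("maximal repeat tract extraction matches brute force", {
  expect_equal(extract_maximal_repeat_region("ACACAC", "AC", 0),
               list(offset = 0L, length = 6L))
  expect_equal(extract_maximal_repeat_region("GGACACACTG", "AC", 0),
               list(offset = 2L, length = 6L))
  expect_equal(extract_maximal_repeat_region("ACACTTTTACACACAC", "AC", 0.05),
               brute_max_tract("ACACTTTTACACACAC", "AC", 0.05))
  expect_null(extract_maximal_repeat_region("GGGG", "AC", 0))

  set.seed(31)
  for (t in 1:40) {
    u <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
               collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), sample(nchar(u):50, 1),
                      replace = TRUE), collapse = "")
    er <- sample(c(0, 0.05, 0.1, 0.2), 1)
    got <- extract_maximal_repeat_region(s, u, er)
    want <- brute_max_tract(s, u, er)
    if (is.null(want)) expect_null(got)
    else expect_equal(got$length, want$length)
  }
})

test_that("error-free extraction equals the longest exact tandem substring", {
  set.seed(32)
  for (t in 1:25) {
    u <- paste(sample(c("A", "C"), sample(1:2, 1), replace = TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G"), 30, replace = TRUE), collapse = "")
    got <- extract_maximal_repeat_region(s, u, 0)
    want <- brute_max_tract(s, u, 0)
    if (is.null(want)) expect_null(got) else {
      expect_equal(got, want) # leftmost tie-break in both
      sub <- substr(s, got$offset + 1, got$offset + got$length)
      expect_equal(sub, substr(strrep(u, ceiling(got$length / nchar(u))),
                               1, got$length))
    }
  }
})

test_that("trim_regions shifts intervals to the clean tract and drops duds", {
  ref <- c(chrZ = paste0("TTTTT", "GG", "ACACACAC", "TG", "TTTTT"))
  reg <- str_regions("chrZ", 5L, 17L, 2L, "AC") # includes the GG prefix
  tr <- trim_regions(reg, ref, error_rate = 0)
  expect_equal(tr$start, 7L)
  expect_equal(tr$end, 15L)
  expect_equal(tr$ref_size, 8L)
  bad <- str_regions("chrZ", 0L, 4L, 2L, "AC")
  expect_warning(out <- trim_regions(bad, ref, error_rate = 0), "dropped")
  expect_equal(nrow(out), 0L)
})
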