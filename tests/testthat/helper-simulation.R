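# Shared benchmark fixture: one synthetic 100 kb reference with ~50 STR
# regions, a diploid genome with randomized repeat numbers, 40x paired-end
# reads (plus a 10x downsample), mapper records and realigned records.
# Built lazily once per test run and cached; several test files reuse it.

.sim_cache <- new.env(parent = emptyenv())

benchmark_fixture <- function() {
  if (!is.null(.sim_cache$fx)) return(.sim_cache$fx)
  syn <- make_synthetic_reference(length = 100000L, n_regions = 50L, seed = 101)
  genome <- simulate_diploid_genome(syn$reference, syn$regions, seed = 102)
  reads40 <- simulate_reads(genome, coverage = 40, seed = 103)
  trimmed <- trim_regions(syn$regions, syn$reference)
  rec40 <- map_simulated_reads(reads40, genome, syn$reference,
                               near = syn$regions)
  out40 <- realign_records(rec40, syn$reference, trimmed)
  set.seed(104) # 10x: keep a quarter of the pairs
  qn <- unique(reads40$qname)
  keep <- reads40$qname %in% sample(qn, length(qn) %/% 4L)
  rec10 <- map_simulated_reads(reads40[keep, , drop = FALSE], genome,
                               syn$reference, near = syn$regions)
  out10 <- realign_records(rec10, syn$reference, trimmed)
  .sim_cache$fx <- list(syn = syn, genome = genome, trimmed = trimmed,
                        rec40 = rec40, out40 = out40,
                        rec10 = rec10, out10 = out10)
  .sim_cache$fx
}

# Small locus fixture used by projection/pipeline unit tests: a single AC
# region with 20 bp flanks.
small_locus <- function(copies_ref = 6L, unit = "AC", seed = 5L) {
  set.seed(seed)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
  f1 <- flank(20); f2 <- flank(20)
  period <- nchar(unit)
  ref <- paste0(f1, strrep(unit, copies_ref), f2)
  names(ref) <- "chrL"
  regions <- str_regions("chrL", 20L, 20L + copies_ref * period, period, unit)
  list(reference = ref, regions = regions, f1 = f1, f2 = f2)
}

# Records whose aligned span overlaps any padded region window.
record_window_overlap <- function(rec, regions, pad) {
  keep <- rep(FALSE, nrow(rec))
  span <- vapply(rec$cigar, strrealign:::cigar_ref_len, numeric(1),
                 USE.NAMES = FALSE)
  for (r in seq_len(nrow(regions)))
    keep <- keep | (rec$rname == regions$chrom[r] &
                      (rec$pos - 1L) < regions$end[r] + pad &
                      (rec$pos - 1L + span) > regions$start[r] - pad)
  keep
}
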