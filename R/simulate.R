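# Synthetic STR benchmark generation: reference + catalog, diploid genomes
# with randomized repeat numbers, and paired-end reads with substitution
# errors.  All functions are deterministic under their seed argument.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# A unit is usable if it is primitive (not a repetition of a shorter word),
# so the catalogued period is unambiguous.
primitive_unit <- function(period) {
  repeat {
    u <- rand_dna(period)
    ok <- TRUE
    for (d in seq_len(period - 1)) {
      if (period %% d != 0) next
      if (strrep(substr(u, 1, d), period / d) == u) { ok <- FALSE; break }
    }
    if (ok) return(u)
  }
}

#' Generate a synthetic reference with an STR catalog
#'
#' Random DNA with `n_regions` pure repeat tracts implanted at well-separated
#' positions, periods cycling over 1..6 and reference tract sizes drawn
#' uniformly from `ref_size_range`.  Bases adjacent to each tract are forced
#' to break the repeat so the catalogued interval is exactly the maximal
#' tract.
#'
#' @param length Reference length in bp (default 100000).
#' @param n_regions Number of STR regions (default 50).
#' @param seed Random seed.
#' @param chrom Reference sequence name.
#' @param ref_size_range Reference tract size bounds in bp (default c(16, 72)).
#' @return List with `reference` (named character vector) and `regions`
#'   (an [str_regions] catalog).
#' @export
make_synthetic_reference <- function(length = 100000L, n_regions = 50L,
                                     seed = 1L, chrom = "chrS",
                                     ref_size_range = c(16L, 72L)) {
  set.seed(seed)
  stopifnot(length / n_regions > 400, ref_size_range[1] >= 12)
  base <- strsplit(rand_dna(length), "", fixed = TRUE)[[1]]
  spacing <- length %/% (n_regions + 1L)
  starts <- integer(n_regions); ends <- integer(n_regions)
  periods <- integer(n_regions); units <- character(n_regions)
  for (r in seq_len(n_regions)) {
    period <- ((r - 1L) %% 6L) + 1L
    unit <- if (period == 1L) rand_dna(1L) else primitive_unit(period)
    lo <- max(1L, ceiling(ref_size_range[1] / period))
    hi <- max(lo, floor(ref_size_range[2] / period))
    copies <- sample(lo:hi, 1L)
    size <- copies * period
    start <- r * spacing + sample(-50L:50L, 1L) # 0-based
    tract <- strsplit(strrep(unit, copies), "", fixed = TRUE)[[1]]
    base[(start + 1L):(start + size)] <- tract
    # break the repeat on both sides
    ub <- strsplit(unit, "", fixed = TRUE)[[1]]
    left_cont <- ub[period] # base that would extend the tract leftwards
    if (base[start] == left_cont)
      base[start] <- sample(setdiff(c("A", "C", "G", "T"), left_cont), 1L)
    right_cont <- ub[1L]
    if (base[start + size + 1L] == right_cont)
      base[start + size + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                                right_cont), 1L)
    starts[r] <- start; ends[r] <- start + size
    periods[r] <- period; units[r] <- unit
  }
  ref <- paste(base, collapse = "")
  names(ref) <- chrom
  list(reference = ref,
       regions = str_regions(chrom, starts, ends, periods, units))
}

#' Simulate a diploid genome with randomized repeat numbers
#'
#' Each haplotype replaces every catalogued tract with a sampled number of
#' unit copies, the number drawn uniformly over the range that keeps the
#' tract size within `(0, max_size]` bp.  Coordinate liftover tables map
#' haplotype to reference positions.
#'
#' @param reference Named character vector (one chromosome).
#' @param regions An [str_regions] catalog (non-overlapping).
#' @param seed Random seed.
#' @param max_size Maximum simulated tract size in bp (default 100).
#' @return List of class `diploid_genome`: `haplotypes` (character vector of
#'   2 sequences), `truth` (per region: `a1`, `a2` allele sizes in bp,
#'   `copies1`, `copies2`, `ref_size`), `liftover` (per haplotype: region
#'   rows with haplotype-coordinate tract bounds), `chrom`.
#' @export
simulate_diploid_genome <- function(reference, regions, seed = 1L,
                                    max_size = 100L) {
  set.seed(seed)
  reference <- as_reference(reference)
  chrom <- unique(regions$chrom)
  stopifnot(length(chrom) == 1L)
  o <- order(regions$start)
  regions <- regions[o, , drop = FALSE]
  if (any(regions$start[-1] < regions$end[-nrow(regions)]))
    stop("regions overlap")
  refseq <- reference[[chrom]]

  copies <- matrix(0L, nrow(regions), 2)
  for (r in seq_len(nrow(regions)))
    for (h in 1:2)
      copies[r, h] <- sample(seq_len(max_size %/% regions$period[r]), 1L)

  haps <- character(2); lift <- vector("list", 2)
  for (h in 1:2) {
    parts <- character(); cur <- 0L; hap_pos <- 0L
    hs <- integer(nrow(regions)); he <- integer(nrow(regions))
    for (r in seq_len(nrow(regions))) {
      gap <- substr(refseq, cur + 1L, regions$start[r])
      parts <- c(parts, gap)
      hap_pos <- hap_pos + nchar(gap)
      hs[r] <- hap_pos
      tract <- strrep(regions$unit[r], copies[r, h])
      parts <- c(parts, tract)
      hap_pos <- hap_pos + nchar(tract)
      he[r] <- hap_pos
      cur <- regions$end[r]
    }
    parts <- c(parts, substr(refseq, cur + 1L, nchar(refseq)))
    haps[h] <- paste(parts, collapse = "")
    lift[[h]] <- data.frame(ref_start = regions$start, ref_end = regions$end,
                            hap_start = hs, hap_end = he)
  }
  truth <- data.frame(chrom = chrom, start = regions$start,
                      end = regions$end, period = regions$period,
                      unit = regions$unit, ref_size = regions$ref_size,
                      copies1 = copies[, 1], copies2 = copies[, 2],
                      a1 = copies[, 1] * regions$period,
                      a2 = copies[, 2] * regions$period,
                      stringsAsFactors = FALSE)
  structure(list(haplotypes = haps, truth = truth, liftover = lift,
                 chrom = chrom), class = "diploid_genome")
}

# Lift a 0-based haplotype position to a 0-based reference position.
# Positions inside a modified tract map into the reference tract, clamped.
lift_to_reference <- function(pos0, lift) {
  k <- findInterval(pos0, lift$hap_start)
  out <- pos0
  pre <- k == 0L
  out[pre] <- pos0[pre]
  for (i in which(!pre)) {
    l <- lift[k[i], ]
    if (pos0[i] < l$hap_end) { # inside the tract
      out[i] <- min(l$ref_start + (pos0[i] - l$hap_start),
                    l$ref_end - 1L)
    } else {
      out[i] <- pos0[i] - l$hap_end + l$ref_end
    }
  }
  out
}

#' Simulate paired-end reads from a diploid genome
#'
#' Fragment starts are uniform over each haplotype; insert lengths are
#' normal (`insert_mean`, `insert_sd`) truncated below at `read_len`;
#' substitution errors are i.i.d. per base at `sub_rate` to a uniformly
#' random different base; all quality characters encode `qual`.  Mate 1 is
#' the forward end of the fragment, mate 2 the reverse-complemented other
#' end.
#'
#' @param genome A [simulate_diploid_genome] object.
#' @param coverage Total read coverage of the (haploid) reference.
#' @param read_len Read length in bp (default 100).
#' @param insert_mean,insert_sd Insert size distribution (default 500, 50).
#' @param sub_rate Per-base substitution error rate (default 0.001).
#' @param qual Phred quality assigned to every base (default 30).
#' @param seed Random seed.
#' @return Data frame with one row per read: `qname`, `mate` (1/2), `hap`,
#'   `hap_pos` (1-based start of the read on its haplotype, forward strand),
#'   `strand`, `seq` (read orientation), `qual`.
#' @export
simulate_reads <- function(genome, coverage = 40, read_len = 100L,
                           insert_mean = 500, insert_sd = 50,
                           sub_rate = 0.001, qual = 30L, seed = 1L) {
  stopifnot(coverage > 0)
  if (insert_mean < read_len) stop("insert_mean must be >= read_len")
  set.seed(seed)
  qs <- strrep(rawToChar(as.raw(qual + 33L)), read_len)
  out <- vector("list", 2)
  for (h in 1:2) {
    hlen <- nchar(genome$haplotypes[h])
    npair <- round(coverage / 2 * hlen / (2 * read_len))
    ins <- pmax(read_len, pmin(hlen, round(stats::rnorm(npair, insert_mean,
                                                        insert_sd))))
    fstart <- vapply(ins, function(i) sample.int(hlen - i + 1L, 1L), integer(1))
    r1 <- substring(genome$haplotypes[h], fstart, fstart + read_len - 1L)
    r2e <- fstart + ins - 1L
    r2 <- substring(genome$haplotypes[h], r2e - read_len + 1L, r2e)
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2)))
    qn <- sprintf("sim_h%d_%06d", h, seq_len(npair))
    out[[h]] <- data.frame(
      qname = rep(qn, 2), mate = rep(1:2, each = npair),
      hap = h, hap_pos = c(fstart, r2e - read_len + 1L),
      strand = rep(c("+", "-"), each = npair),
      seq = c(r1, r2), qual = qs, stringsAsFactors = FALSE)
  }
  reads <- rbind(out[[1]], out[[2]])
  reads$seq <- add_substitution_errors(reads$seq, sub_rate)
  reads
}

add_substitution_errors <- function(seqs, sub_rate) {
  if (sub_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), sub_rate)
  for (i in which(n_err > 0L)) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(b), n_err[i])
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
    seqs[i] <- paste(b, collapse = "")
  }
  seqs
}

#' Write simulated reads as paired FASTQ files
#'
#' @param reads Data frame from [simulate_reads].
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, "_", 1:2, ".fastq")
  for (m in 1:2) {
    r <- reads[reads$mate == m, , drop = FALSE]
    writeLines(rbind(paste0("@", r$qname, "/", m), r$seq, "+", r$qual)[TRUE],
               paths[m])
  }
  invisible(paths)
}
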