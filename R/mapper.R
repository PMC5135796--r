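#' Map simulated reads to the reference (emulated seed-and-extend mapper)
#'
#' Produces the pre-realignment alignments for simulation studies.  Each
#' read is placed by an exact seed in one of its flanks — the placement a
#' seed-and-extend mapper derives — and then extended without gaps: the
#' best-scoring contiguous segment under the match/mismatch/clip penalties
#' is aligned and the remainder soft-clipped.  Two candidate placements are
#' tried (read anchored by its left or its right end, lifted from the known
#' simulated origin) and the better one kept.
#'
#' This reproduces the characteristic mapper pathology at STR loci that
#' repeat-aware realignment repairs: reads carrying a non-reference repeat
#' length align cleanly over one flank and are soft-clipped over the other,
#' instead of carrying the repeat-length insertion or deletion.  Reads away
#' from any catalogued region align all-match.
#'
#' @param reads Data frame from [simulate_reads].
#' @param genome The [simulate_diploid_genome] object the reads came from.
#' @param reference Named character vector (the simulated reference).
#' @param pen A [penalty_scheme] (match/mismatch/clip are used).
#' @param near Optional [str_regions] catalog: only reads whose placed span
#'   overlaps a region padded by `near_pad` are emitted (keeps benchmark
#'   runtimes proportional to the catalog, not the genome).
#' @param near_pad Padding for `near` (default 150).
#' @return Records data frame in [read_bam_records] layout.
#' @export
map_simulated_reads <- function(reads, genome, reference,
                                pen = penalty_scheme(),
                                near = NULL, near_pad = 150L) {
  reference <- as_reference(reference)
  pen <- as_penalty_scheme(pen)
  chrom <- genome$chrom
  refseq <- reference[[chrom]]
  reflen <- nchar(refseq)
  rlen <- nchar(reads$seq)

  left_anchor <- integer(nrow(reads)); right_anchor <- integer(nrow(reads))
  for (h in 1:2) {
    ih <- reads$hap == h
    left_anchor[ih] <- lift_to_reference(reads$hap_pos[ih] - 1L,
                                         genome$liftover[[h]])
    right_anchor[ih] <- lift_to_reference(reads$hap_pos[ih] - 1L + rlen[ih] - 1L,
                                          genome$liftover[[h]]) - (rlen[ih] - 1L)
  }

  keep <- rep(TRUE, nrow(reads))
  if (!is.null(near)) {
    keep <- rep(FALSE, nrow(reads))
    for (r in seq_len(nrow(near))) {
      keep <- keep | (pmin(left_anchor, right_anchor) < near$end[r] + near_pad &
                        (pmax(left_anchor, right_anchor) + rlen) >
                          near$start[r] - near_pad)
    }
    # keep whole pairs so mate fields stay meaningful
    keep <- reads$qname %in% unique(reads$qname[keep])
  }

  idx <- which(keep)
  pos <- integer(length(idx)); cig <- character(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    seq <- if (reads$strand[i] == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(reads$seq[i])))
    else reads$seq[i]
    best <- NULL
    for (anchor in unique(c(left_anchor[i], right_anchor[i]))) {
      fit <- gapless_fit(seq, refseq, anchor, reflen, pen)
      if (is.null(best) || fit$penalty < best$penalty) best <- fit
    }
    pos[q] <- best$pos; cig[q] <- best$cigar
  }

  reads <- reads[idx, , drop = FALSE]
  flag <- 1L + 2L +
    ifelse(reads$mate == 1L, 64L, 128L) +
    ifelse(reads$strand == "-", 16L, 32L)
  seqs <- ifelse(reads$strand == "-",
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAStringSet(reads$seq))),
                 reads$seq)
  rec <- data.frame(
    qname = reads$qname, flag = flag, rname = chrom, pos = pos + 1L,
    mapq = 60L, cigar = cig, rnext = chrom, pnext = 0L, tlen = 0L,
    seq = seqs, qual = reads$qual, tags = "", stringsAsFactors = FALSE)

  # mate coordinates
  key <- paste(rec$qname, ifelse(bitwAnd(rec$flag, 64L) > 0L, 2L, 1L))
  own <- paste(rec$qname, ifelse(bitwAnd(rec$flag, 64L) > 0L, 1L, 2L))
  mate_pos <- rec$pos[match(key, own)]
  rec$pnext <- ifelse(is.na(mate_pos), 0L, mate_pos)
  o <- order(rec$pos, rec$qname)
  rec[o, , drop = FALSE]
}

# Gap-free fitting of a read at a fixed reference placement: the aligned
# part is the contiguous read segment minimizing match/mismatch penalties
# plus one flat clip charge per clipped end; out-of-bounds overhang is
# forced into the clips.
gapless_fit <- function(seq, refseq, anchor, reflen, pen) {
  n <- nchar(seq)
  a_min <- max(0L, -anchor)                   # forced left clip
  b_max <- min(n, reflen - anchor)            # last alignable read position
  if (b_max - a_min < 1L)                     # placement entirely off contig
    return(list(penalty = Inf, pos = 0L, cigar = paste0(n, "S")))
  t <- substr(refseq, anchor + a_min + 1L, anchor + b_max)
  q <- substr(seq, a_min + 1L, b_max)
  mism <- strsplit(q, "", fixed = TRUE)[[1]] != strsplit(t, "", fixed = TRUE)[[1]]
  cost <- ifelse(mism, pen$mismatch, pen$match)
  m <- length(cost)
  C <- c(0, cumsum(cost))                      # C[a+1] = sum of first a costs
  # segment [a+1, b]: C[b+1] - C[a+1] + clip charges; left clip charged when
  # a + a_min > 0, right clip when b < m or b_max < n.
  lc <- ifelse(seq_len(m + 1L) - 1L + a_min > 0L, pen$clip, 0)
  pre <- cummin(C + lc)                        # best left part for each b
  pre_arg <- integer(m + 1L); best <- Inf
  for (a in 0:m) {                             # argmin bookkeeping
    v <- C[a + 1L] + lc[a + 1L]
    if (v < best) { best <- v; cur <- a }
    pre_arg[a + 1L] <- cur
  }
  rc <- ifelse(seq_len(m + 1L) - 1L < m | b_max < n, pen$clip, 0)
  # evaluate all b = 1..m with their best a < b
  bestv <- Inf; bestb <- 1L
  for (b in 1:m) {
    v <- C[b + 1L] + rc[b + 1L] + pre[b]       # a in 0..b-1
    if (v < bestv) { bestv <- v; bestb <- b }
  }
  a <- pre_arg[bestb]                          # a in 0..bestb-1
  left <- a + a_min; right <- n - (bestb + a_min)
  list(penalty = bestv,
       pos = anchor + left,
       cigar = collapse_cigar(c("S", "M", "S"),
                              c(left, bestb - a, right)))
}
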