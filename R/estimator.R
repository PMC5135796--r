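#' Naive spanning-read STR size estimator
#'
#' A deliberately simple diploid STR size caller used to evaluate
#' realignment quality end to end without any external genotyper: for every
#' read whose alignment fully spans a region plus `flank_margin` bp of each
#' flank, the region size implied by its CIGAR is
#' `ref_size + insertions - deletions` inside the region.  The two most
#' frequent implied sizes are called (one, homozygous, if a single size
#' holds at least `hom_frac` of the spanning reads); regions with fewer than
#' `min_span` spanning reads are called NA.
#'
#' @param rec Records data frame ([read_bam_records] layout) or a BAM path.
#' @param regions An [str_regions] catalog (the evaluation regions).
#' @param min_span Minimum spanning reads for a call (default 3).
#' @param flank_margin Required flank coverage in bp (default 5).
#' @param hom_frac Mode fraction above which the call is homozygous
#'   (default 0.7).
#' @return Data frame: `chrom`, `start`, `end`, `period`, `ref_size`,
#'   `a1`, `a2` (bp; NA when uncallable), `n_span`.
#' @export
naive_spanning_estimator <- function(rec, regions, min_span = 3L,
                                     flank_margin = 5L, hom_frac = 0.7) {
  if (is.character(rec)) rec <- read_bam_records(rec)
  span_len <- vapply(rec$cigar, cigar_ref_len, numeric(1), USE.NAMES = FALSE)
  out <- regions[, c("chrom", "start", "end", "period", "ref_size")]
  out$a1 <- NA_integer_; out$a2 <- NA_integer_; out$n_span <- 0L
  primary <- !is.na(rec$pos) & bitwAnd(rec$flag, 0x904L) == 0L
  for (r in seq_len(nrow(regions))) {
    s <- regions$start[r]; e <- regions$end[r]
    sel <- which(primary & rec$rname == regions$chrom[r] &
                   (rec$pos - 1L) <= s - flank_margin &
                   (rec$pos - 1L + span_len) >= e + flank_margin)
    out$n_span[r] <- length(sel)
    if (length(sel) < min_span) next
    sizes <- vapply(sel, function(i)
      implied_region_size(rec$cigar[i], rec$pos[i] - 1L, s, e), integer(1))
    tab <- sort(table(sizes), decreasing = TRUE)
    vals <- as.integer(names(tab))
    if (tab[1] / length(sizes) >= hom_frac || length(tab) == 1L) {
      out$a1[r] <- vals[1]; out$a2[r] <- vals[1]
    } else {
      ab <- sort(vals[1:2])
      out$a1[r] <- ab[1]; out$a2[r] <- ab[2]
    }
  }
  out
}

# Region size implied by one alignment: ref_size plus insertions anchored in
# [start, end] minus deleted reference bases in [start, end).
implied_region_size <- function(cigar, pos0, start, end) {
  cg <- parse_cigar(cigar)
  rp <- pos0; ins <- 0L; del <- 0L
  for (r in seq_len(nrow(cg))) {
    op <- cg$op[r]; len <- cg$len[r]
    if (op %in% c("M", "=", "X")) {
      rp <- rp + len
    } else if (op == "I") {
      if (rp >= start && rp <= end) ins <- ins + len
    } else if (op %in% c("D", "N")) {
      del <- del + max(0L, min(rp + len, end) - max(rp, start))
      rp <- rp + len
    }
  }
  as.integer(end - start + ins - del)
}
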