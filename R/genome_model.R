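#' Build a repeat-aware genome model for a locus
#'
#' The alignment target of the realigner is not the raw reference but a model
#' of the locus: an ordered series of subsequences in which flanking
#' reference sequence appears literally (used once) and each STR region is
#' represented by a single copy of its repeat unit flagged as reusable
#' (traversable cyclically any number of times).  Adjacent regions with no
#' intervening reference yield consecutive reusable subsequences.
#'
#' @param reference Reference sequences (named character vector,
#'   `DNAStringSet`, or FASTA path).
#' @param regions An [str_regions] data frame; all on one chromosome, sorted
#'   and non-overlapping (normally the trimmed regions of one locus
#'   neighborhood).
#' @param flank Flank length in bp taken on the outer edges (default 101,
#'   one read length).
#' @return An object of class `genome_model`: a list with `chrom`,
#'   `window` (0-based half-open model span) and `subsequences`, a data frame
#'   with columns `seq`, `repeat_flag`, `ref_start`, `ref_end`, `origin`,
#'   `region_idx` (row of `regions` for repeat-unit subsequences).
#' @examples
#' ref <- c(chrA = paste0(strrep("T", 12), strrep("AC", 5), strrep("G", 12)))
#' reg <- str_regions("chrA", 12, 22, 2, "AC")
#' build_genome_model(ref, reg, flank = 10)
#' @export
build_genome_model <- function(reference, regions, flank = 101L) {
  stopifnot(nrow(regions) >= 1, flank >= 1)
  reference <- as_reference(reference)
  chrom <- unique(regions$chrom)
  if (length(chrom) != 1L) stop("all regions must be on one chromosome")
  o <- order(regions$start)
  regions <- regions[o, , drop = FALSE]
  if (any(regions$start[-1] < regions$end[-nrow(regions)]))
    stop("regions overlap")
  seqlen <- nchar(reference[[chrom]])
  if (regions$start[1] < 0 || regions$end[nrow(regions)] > seqlen)
    stop("region outside reference bounds")

  win_start <- max(0L, regions$start[1] - as.integer(flank))
  win_end <- min(seqlen, regions$end[nrow(regions)] + as.integer(flank))

  seqs <- character(); repf <- logical()
  rs <- integer(); re <- integer(); orig <- character(); ridx <- integer()
  add <- function(seq, flag, a, b, origin, idx) {
    if (!flag && nchar(seq) == 0L) return(invisible())
    seqs <<- c(seqs, seq); repf <<- c(repf, flag)
    rs <<- c(rs, a); re <<- c(re, b)
    orig <<- c(orig, origin); ridx <<- c(ridx, idx)
    invisible()
  }
  cur <- win_start
  for (r in seq_len(nrow(regions))) {
    if (regions$start[r] > cur)
      add(ref_subseq(reference, chrom, cur, regions$start[r]), FALSE,
          cur, regions$start[r], "flank", NA_integer_)
    add(regions$unit[r], TRUE, regions$start[r], regions$end[r],
        "repeat_unit", r)
    cur <- regions$end[r]
  }
  if (win_end > cur)
    add(ref_subseq(reference, chrom, cur, win_end), FALSE,
        cur, win_end, "flank", NA_integer_)

  structure(list(
    chrom = chrom,
    window = c(start = win_start, end = win_end),
    regions = regions,
    subsequences = data.frame(
      seq = seqs, repeat_flag = repf, ref_start = rs, ref_end = re,
      origin = orig, region_idx = ridx, stringsAsFactors = FALSE)),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  ss <- x$subsequences
  cat(sprintf("Genome model on %s:%d-%d, %d subsequences (%d reusable)\n",
              x$chrom, x$window[["start"]], x$window[["end"]],
              nrow(ss), sum(ss$repeat_flag)))
  for (j in seq_len(nrow(ss))) {
    s <- ss$seq[j]
    if (nchar(s) > 24) s <- paste0(substr(s, 1, 24), "...")
    cat(sprintf("  G%-2d B=%d %-8s %s\n", j, as.integer(ss$repeat_flag[j]),
                ss$origin[j], s))
  }
  invisible(x)
}
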