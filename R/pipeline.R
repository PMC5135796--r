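#' Realign a BAM over catalogued STR regions
#'
#' End-to-end realignment: the catalog is trimmed to clean repeat tracts,
#' long homopolymer regions are optionally skipped, nearby regions are merged
#' into loci, and every primary mapped read overlapping a padded locus is
#' realigned against the locus's repeat-aware genome model and projected back
#' to reference coordinates.  A read is rewritten only when the projected
#' alignment scores strictly better than its original alignment rescored with
#' the same penalties (fail-safe: realignment never makes a record worse, and
#' a second pass reproduces the first).  Rewritten records carry their
#' original position and CIGAR in `OP`/`OC` tags; all other records are
#' copied verbatim.
#'
#' @param in_bam Input coordinate-sorted, indexed BAM.
#' @param reference Reference sequences (named character vector,
#'   `DNAStringSet`, or FASTA path).
#' @param regions STR catalog: an [str_regions] data frame or a catalog path.
#' @param out_bam Output BAM path (sorted and indexed).
#' @param pen A [penalty_scheme].
#' @param flank Model flank length in bp (default 101).
#' @param pad Read-selection padding in bp (default 101).
#' @param error_rate Repeat-tract trimming error rate (default 0.1).
#' @param homopolymer_skip Skip homopolymer regions at least this long
#'   (default 15); `NA` disables the skip.
#' @param min_aligned Reads clipped on both ends with fewer aligned bases
#'   than this keep their original alignment (default 20).
#' @return Invisibly, a list with `out_bam`, `n_realigned`, `n_kept`,
#'   `regions` (the surviving trimmed catalog) and `log` (per-locus counts).
#' @export
realign_bam <- function(in_bam, reference, regions, out_bam,
                        pen = penalty_scheme(), flank = 101L, pad = 101L,
                        error_rate = 0.1, homopolymer_skip = 15L,
                        min_aligned = 20L) {
  reference <- as_reference(reference)
  if (is.character(regions)) regions <- read_str_catalog(regions)
  if (nrow(regions) == 0L) stop("catalog is empty")
  regions <- trim_regions(regions, reference, error_rate)
  if (!is.na(homopolymer_skip))
    regions <- regions[!is_long_homopolymer(regions, homopolymer_skip), ,
                       drop = FALSE]
  rec <- read_bam_records(in_bam)
  out <- realign_records(rec, reference, regions, pen = pen, flank = flank,
                         pad = pad, min_aligned = min_aligned)
  write_bam_records(out$records, vapply(reference, nchar, integer(1)), out_bam)
  invisible(list(out_bam = out_bam, n_realigned = out$n_realigned,
                 n_kept = out$n_kept, regions = regions, log = out$log))
}

#' Realign in-memory records over a trimmed catalog
#'
#' The in-memory core of [realign_bam]; exposed so simulation studies can
#' avoid intermediate BAM files.
#'
#' @inheritParams realign_bam
#' @param rec Records data frame ([read_bam_records] layout).
#' @return List with `records` (same layout, realigned where improved),
#'   `n_realigned`, `n_kept`, `log`.
#' @export
realign_records <- function(rec, reference, regions, pen = penalty_scheme(),
                            flank = 101L, pad = 101L, min_aligned = 20L) {
  reference <- as_reference(reference)
  pen <- as_penalty_scheme(pen)
  loci <- group_loci(regions, pad)
  n_realigned <- 0L; n_kept <- 0L
  log <- data.frame(locus = integer(), n_reads = integer(),
                    n_rewritten = integer())
  touched <- rep(FALSE, nrow(rec))

  for (li in seq_along(loci)) {
    lr <- loci[[li]]
    wstart <- min(lr$start) - pad
    wend <- max(lr$end) + pad
    sel <- which(record_overlaps(rec, lr$chrom[1], wstart, wend) & !touched)
    if (length(sel) == 0L) next
    model <- build_genome_model(reference, lr, flank = flank)
    refchrom <- reference[[lr$chrom[1]]]
    nrw <- 0L
    for (ri in sel) {
      touched[ri] <- TRUE
      seq <- rec$seq[ri]
      if (grepl("[^ACGT]", seq)) seq <- gsub("[^ACGT]", "N", toupper(seq))
      aln <- try(realign(seq, model, pen), silent = TRUE)
      if (inherits(aln, "try-error")) { n_kept <- n_kept + 1L; next }
      aligned <- nchar(seq) - aln$left_clip - aln$right_clip
      if (aln$left_clip > 0L && aln$right_clip > 0L && aligned < min_aligned) {
        n_kept <- n_kept + 1L; next
      }
      proj <- project_to_reference(aln, model, reference, pen)
      if (!isTRUE(proj$ok)) { n_kept <- n_kept + 1L; next }
      orig_pen <- score_reference_alignment(seq, refchrom, rec$pos[ri] - 1L,
                                            rec$cigar[ri], pen)
      if (proj$penalty < orig_pen) {
        tag <- sprintf("OP:i:%d\tOC:Z:%s", rec$pos[ri], rec$cigar[ri])
        rec$tags[ri] <- if (!is.na(rec$tags[ri]) && nzchar(rec$tags[ri]))
          paste(rec$tags[ri], tag, sep = "\t") else tag
        rec$pos[ri] <- proj$pos + 1L
        rec$cigar[ri] <- proj$cigar
        n_realigned <- n_realigned + 1L
        nrw <- nrw + 1L
      } else {
        n_kept <- n_kept + 1L
      }
    }
    log <- rbind(log, data.frame(locus = li, n_reads = length(sel),
                                 n_rewritten = nrw))
  }

  rec <- update_mates(rec, touched)
  o <- order(is.na(rec$pos), rec$rname, rec$pos, rec$qname)
  list(records = rec[o, , drop = FALSE], n_realigned = n_realigned,
       n_kept = n_kept, log = log)
}

# Merge regions whose padded windows overlap into loci (lists of
# str_regions rows); a read spanning two nearby regions is then realigned
# once against a merged model.
group_loci <- function(regions, pad) {
  if (nrow(regions) == 0L) return(list())
  o <- order(regions$chrom, regions$start)
  regions <- regions[o, , drop = FALSE]
  loci <- list()
  cur <- regions[1, , drop = FALSE]
  cur_end <- cur$end + 2L * pad
  for (r in seq_len(nrow(regions))[-1]) {
    if (regions$chrom[r] == cur$chrom[1] && regions$start[r] < cur_end) {
      cur <- rbind(cur, regions[r, , drop = FALSE])
    } else {
      loci[[length(loci) + 1L]] <- cur
      cur <- regions[r, , drop = FALSE]
    }
    cur_end <- regions$end[r] + 2L * pad
  }
  loci[[length(loci) + 1L]] <- cur
  loci
}

# When both mates of a pair were rewritten in this run, refresh their mate
# positions; otherwise mate fields are left as stored.
update_mates <- function(rec, touched) {
  if (!any(touched)) return(rec)
  idx <- which(touched)
  by_name <- split(idx, rec$qname[idx])
  for (nm in names(by_name)) {
    ii <- by_name[[nm]]
    if (length(ii) != 2L) next
    rec$pnext[ii[1]] <- rec$pos[ii[2]]
    rec$pnext[ii[2]] <- rec$pos[ii[1]]
  }
  rec
}
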