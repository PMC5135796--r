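# BAM input/output.  Records travel through the pipeline as a plain
# data.frame (one row per alignment record, SAM column names, 1-based pos);
# htslib (via Rsamtools) does the binary work on both ends.

#' Read all records of a BAM file into a data frame
#'
#' @param bam Path to a BAM file.
#' @return A data.frame with SAM-like columns: `qname`, `flag`, `rname`,
#'   `pos` (1-based; NA for unmapped), `mapq`, `cigar`, `rnext`, `pnext`,
#'   `tlen`, `seq`, `qual`, `tags` (character, possibly "").
#' @export
read_bam_records <- function(bam) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq", "qual"),
    tag = c("OP", "OC"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  tags <- character(length(x$qname))
  if (!is.null(x$tag$OP)) {
    op <- x$tag$OP
    tags <- ifelse(is.na(op), tags, paste0(tags, "OP:i:", op, "\t"))
  }
  if (!is.null(x$tag$OC)) {
    oc <- x$tag$OC
    tags <- ifelse(is.na(oc), tags, paste0(tags, "OC:Z:", oc, "\t"))
  }
  data.frame(
    qname = x$qname, flag = x$flag,
    rname = as.character(x$rname), pos = x$pos,
    mapq = x$mapq, cigar = x$cigar,
    rnext = as.character(x$mrnm), pnext = x$mpos, tlen = x$isize,
    seq = as.character(x$seq), qual = as.character(x$qual),
    tags = sub("\t$", "", tags),
    stringsAsFactors = FALSE)
}

#' Write alignment records to a coordinate-sorted, indexed BAM
#'
#' @param records Data frame as returned by [read_bam_records].
#' @param seqinfo Named integer vector of reference sequence lengths.
#' @param out_bam Output BAM path (a .bai index is written alongside).
#' @return `out_bam`, invisibly.
#' @export
write_bam_records <- function(records, seqinfo, out_bam) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo), as.integer(seqinfo)))
  rnext <- ifelse(is.na(records$rnext), "*",
                  ifelse(records$rnext == records$rname & !is.na(records$rname),
                         "=", records$rnext))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  records$qname, records$flag,
                  ifelse(is.na(records$rname), "*", records$rname),
                  ifelse(is.na(records$pos), 0L, records$pos),
                  ifelse(is.na(records$mapq), 0L, records$mapq),
                  ifelse(is.na(records$cigar), "*", records$cigar),
                  rnext,
                  ifelse(is.na(records$pnext), 0L, records$pnext),
                  ifelse(is.na(records$tlen), 0L, records$tlen),
                  records$seq, records$qual)
  hastag <- !is.na(records$tags) & nzchar(records$tags)
  body[hastag] <- paste(body[hastag], records$tags[hastag], sep = "\t")
  writeLines(c(hdr, body), sam)
  tmp <- tempfile()
  bam0 <- Rsamtools::asBam(sam, tmp, overwrite = TRUE, indexDestination = FALSE)
  out_prefix <- sub("\\.bam$", "", out_bam)
  Rsamtools::sortBam(bam0, out_prefix)
  unlink(bam0)
  Rsamtools::indexBam(out_bam)
  invisible(out_bam)
}

#' Select reads overlapping a padded STR region
#'
#' Returns every primary, mapped record whose alignment span overlaps
#' `[start - pad, end + pad)`.  Secondary and supplementary records are
#' excluded; unmapped mates are untouched.
#'
#' @param bam Path to an indexed BAM file.
#' @param region A single-row [str_regions] data frame.
#' @param pad Padding in bp (default 101).
#' @return Data frame of selected records (see [read_bam_records]).
#' @export
select_reads <- function(bam, region, pad = 101L) {
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index not found for ", bam)
  rec <- read_bam_records(bam)
  keep <- record_overlaps(rec, region$chrom, region$start - pad,
                          region$end + pad)
  rec[keep, , drop = FALSE]
}

# Primary mapped records overlapping a 0-based half-open reference window.
record_overlaps <- function(rec, chrom, wstart, wend) {
  primary <- !is.na(rec$pos) &
    bitwAnd(rec$flag, 0x4L) == 0L &
    bitwAnd(rec$flag, 0x100L) == 0L &
    bitwAnd(rec$flag, 0x800L) == 0L
  span <- vapply(rec$cigar, cigar_ref_len, numeric(1), USE.NAMES = FALSE)
  s <- rec$pos - 1L
  primary & !is.na(rec$rname) & rec$rname == chrom &
    s < wend & (s + span) > wstart
}
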