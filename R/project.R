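#' Project a model alignment to reference coordinates
#'
#' Translates an alignment against the repeat-aware genome model into a
#' standard reference CIGAR.  Flank-aligned segments translate positionally.
#' Each repeat-aligned read fragment is realigned (same affine machinery,
#' no reusable subsequences) against the reference STR region sequence plus
#' one trailing repeat-unit copy, with the region's deletion-open penalty
#' lowered to `pen$str_del_open`; fragment bases aligned to the trailing unit
#' project as insertions.  Regions traversed with zero unit copies and
#' repeat subsequences skipped at boundaries project as deletions.  Clips
#' become soft clips.
#'
#' @param aln A `model_alignment` from [realign].
#' @param model The [build_genome_model] the alignment was computed against.
#' @param reference Reference sequences (named character vector,
#'   `DNAStringSet`, or FASTA path).
#' @param pen A [penalty_scheme].
#' @return A list with `chrom`, `pos` (0-based leftmost reference position),
#'   `cigar`, `penalty` (the projected alignment rescored against the
#'   reference with `pen`) and `ok` (FALSE when stitching produced an
#'   inconsistent alignment, in which case the caller should keep the
#'   original record).
#' @export
project_to_reference <- function(aln, model, reference, pen = penalty_scheme()) {
  pen <- as_penalty_scheme(pen)
  reference <- as_reference(reference)
  ss <- model$subsequences
  path <- aln$path
  rb <- strsplit(toupper(aln$read$seq), "", fixed = TRUE)[[1]]

  core <- path[path[, "kind"] %in% c(1L, 2L, 3L), , drop = FALSE]
  if (nrow(core) == 0L) return(list(ok = FALSE))
  segs <- split(seq_len(nrow(core)), cumsum(c(TRUE, diff(core[, "j"]) != 0L)))

  op <- character(); len <- integer(); rpos <- integer() # rpos: ref pos of op start (NA for I)
  emit <- function(o, l, p) {
    op <<- c(op, o); len <<- c(len, l); rpos <<- c(rpos, p)
  }

  for (si in seq_along(segs)) {
    rows <- core[segs[[si]], , drop = FALSE]
    j <- rows[1, "j"]
    if (!ss$repeat_flag[j]) {
      for (r in seq_len(nrow(rows))) {
        kind <- rows[r, "kind"]
        if (kind == 1L) emit("M", 1L, ss$ref_start[j] + rows[r, "k"] - 1L)
        else if (kind == 2L) emit("I", 1L, NA_integer_)
        else emit("D", 1L, ss$ref_start[j] + rows[r, "k"] - 1L)
      }
    } else {
      frag <- paste0(rb[rows[rows[, "kind"] %in% c(1L, 2L), "i"]], collapse = "")
      if (nchar(frag) == 0L) next
      rg <- model$regions[ss$region_idx[j], , drop = FALSE]
      region_seq <- ref_subseq(reference, model$chrom, rg$start, rg$end)
      fa <- align_fragment_cpp(frag, region_seq, rg$unit,
                               pen$match, pen$mismatch,
                               pen$ins_open, pen$ins_ext,
                               pen$str_del_open, pen$del_open, pen$del_ext,
                               anchor_left = si > 1L,
                               anchor_right = si < length(segs))
      base <- rg$start + fa$ref_offset
      for (r in seq_along(fa$op)) {
        o <- fa$op[r]; l <- fa$len[r]
        if (o == "I") emit("I", l, NA_integer_)
        else { emit(o, l, base); base <- base + l }
      }
    }
  }

  # Stitch: walk ref-consuming ops in order, inserting deletions over skipped
  # reference (zero-copy regions, boundary-skipped repeat subsequences).
  sop <- character(); slen <- integer()
  cur <- NA_integer_; pos <- NA_integer_
  for (r in seq_along(op)) {
    if (op[r] == "I") { sop <- c(sop, "I"); slen <- c(slen, len[r]); next }
    p <- rpos[r]
    if (is.na(cur)) {
      pos <- p
    } else if (p > cur) {
      sop <- c(sop, "D"); slen <- c(slen, p - cur)
    } else if (p < cur) {
      return(list(ok = FALSE)) # inconsistent stitch
    }
    sop <- c(sop, op[r]); slen <- c(slen, len[r])
    cur <- p + len[r]
  }
  if (length(sop) == 0L || !any(sop == "M")) return(list(ok = FALSE))

  # Trim leading/trailing deletions (and leading insertions fold into pos).
  while (length(sop) && sop[1] == "D") {
    pos <- pos + slen[1]; sop <- sop[-1]; slen <- slen[-1]
  }
  while (length(sop) && sop[length(sop)] == "D") {
    sop <- sop[-length(sop)]; slen <- slen[-length(slen)]
  }

  if (aln$left_clip > 0L) { sop <- c("S", sop); slen <- c(aln$left_clip, slen) }
  if (aln$right_clip > 0L) { sop <- c(sop, "S"); slen <- c(slen, aln$right_clip) }

  cigar <- collapse_cigar(sop, slen)
  if (cigar_query_len(cigar) != length(rb)) return(list(ok = FALSE))

  pos <- unname(pos)
  penalty <- score_reference_alignment(aln$read$seq, reference[[model$chrom]],
                                       pos, cigar, pen)
  list(chrom = model$chrom, pos = pos, cigar = cigar,
       penalty = penalty, ok = TRUE)
}
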