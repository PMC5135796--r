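# CIGAR helpers over the M/I/D/S alphabet used by this package.

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(data.frame(op = character(), len = integer()))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

collapse_cigar <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (length(op) == 0L) return("*")
  # merge adjacent equal ops
  grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
  len <- tapply(len, grp, sum)
  op <- op[!duplicated(grp)]
  paste0(as.integer(len), op, collapse = "")
}

cigar_query_len <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
}

cigar_ref_len <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

#' Score a reference alignment
#'
#' Re-scores a standard CIGAR alignment of a read against the reference with
#' a [penalty_scheme]: per-base match/mismatch over M ops, affine charges for
#' I/D runs, and the flat clip penalty once per soft-clip event.  Used to
#' compare a realigned read with its original alignment on an equal footing.
#'
#' @param seq Read sequence (as stored in the record, reference orientation).
#' @param refseq Reference chromosome sequence (character scalar).
#' @param pos 0-based leftmost reference position of the alignment.
#' @param cigar CIGAR string (M/I/D/S ops; =/X are treated as M).
#' @param pen A [penalty_scheme].
#' @return Total penalty (numeric scalar).
#' @export
score_reference_alignment <- function(seq, refseq, pos, cigar,
                                      pen = penalty_scheme()) {
  pen <- as_penalty_scheme(pen)
  cg <- parse_cigar(cigar)
  qp <- 0L; rp <- pos # query consumed, current ref pos (0-based)
  total <- 0
  for (r in seq_len(nrow(cg))) {
    op <- cg$op[r]; len <- cg$len[r]
    if (op %in% c("M", "=", "X")) {
      q <- substr(seq, qp + 1L, qp + len)
      t <- substr(refseq, rp + 1L, rp + len)
      nmis <- sum(strsplit(q, "")[[1]] != strsplit(t, "")[[1]])
      total <- total + nmis * pen$mismatch + (len - nmis) * pen$match
      qp <- qp + len; rp <- rp + len
    } else if (op == "I") {
      total <- total + pen$ins_open + (len - 1L) * pen$ins_ext
      qp <- qp + len
    } else if (op == "D" || op == "N") {
      total <- total + pen$del_open + (len - 1L) * pen$del_ext
      rp <- rp + len
    } else if (op == "S") {
      total <- total + pen$clip
      qp <- qp + len
    } else if (op != "H" && op != "P") {
      stop("unsupported CIGAR op: ", op)
    }
  }
  total
}
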