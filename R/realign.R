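#' Realign a read against a repeat-aware genome model
#'
#' Runs the realignment dynamic program: the read is aligned to the model's
#' subsequence series under fitting semantics (unaligned model prefix/suffix
#' are free), with affine gap penalties, cyclic reuse of repeat-unit
#' subsequences (including traversing them zero times), rotating multi-base
#' deletions of fewer than one unit length inside repeat units, and
#' flat-penalty left/right clipping.  The minimum total penalty and its state
#' path are returned.
#'
#' @param read Character scalar (read sequence) or a list with elements
#'   `name`, `seq`, `qual`.
#' @param model A [build_genome_model] object.
#' @param pen A [penalty_scheme].
#' @param clip Logical: allow clip states (default TRUE).
#' @param materialize_dmulti Logical: store multi-deletion states explicitly
#'   instead of reconstructing them on demand from the closed form (the two
#'   modes are equivalent; on-demand is the default and uses linear space in
#'   the model length).
#' @return An object of class `model_alignment`: list with `penalty`, `path`
#'   (matrix with columns kind/i/j/k/l; kinds 1=M, 2=I, 3=D, 4=left clip,
#'   5=right clip), `left_clip`, `right_clip`, `n_updates`, `read`.
#' @examples
#' ref <- c(chrA = paste0(strrep("T", 10), strrep("AC", 4), strrep("G", 10)))
#' reg <- str_regions("chrA", 10, 18, 2, "AC")
#' m <- build_genome_model(ref, reg, flank = 10)
#' realign(paste0("TT", strrep("AC", 6), "GG"), m)$penalty
#' @export
realign <- function(read, model, pen = penalty_scheme(), clip = TRUE,
                    materialize_dmulti = FALSE) {
  if (is.character(read)) read <- list(name = "read", seq = read, qual = NULL)
  seq <- toupper(read$seq)
  if (nchar(seq) < 1L) stop("read must have at least one base")
  pen <- as_penalty_scheme(pen)
  ss <- model$subsequences
  m <- nrow(ss)
  res <- dp_realign_cpp(seq, ss$seq, ss$repeat_flag,
                        rep(pen$match, m), rep(pen$mismatch, m),
                        rep(pen$ins_open, m), rep(pen$ins_ext, m),
                        rep(pen$del_open, m), rep(pen$del_ext, m),
                        pen$clip, isTRUE(clip), isTRUE(materialize_dmulti))
  structure(list(penalty = res$penalty, path = res$path,
                 left_clip = res$left_clip, right_clip = res$right_clip,
                 n_updates = res$n_updates, read = read, pen = pen),
            class = "model_alignment")
}

#' @export
print.model_alignment <- function(x, ...) {
  k <- x$path[, "kind"]
  cat(sprintf("Model alignment: penalty %g; %d M, %d I, %d D, clips %d/%d\n",
              x$penalty, sum(k == 1), sum(k == 2), sum(k == 3),
              x$left_clip, x$right_clip))
  invisible(x)
}

#' Re-score a model alignment path
#'
#' Sums per-state penalties of a traceback path independently of the dynamic
#' program: matches/mismatches are looked up against the model, insertion and
#' deletion runs are charged open + (length-1) * extension, clips are charged
#' the flat clip penalty once per event.  Used as a self-consistency check of
#' the engine.
#'
#' @param aln A `model_alignment`.
#' @param model The model it was computed against.
#' @param pen The penalty scheme (defaults to the one stored in `aln`).
#' @return The total penalty (numeric scalar).
#' @export
alignment_penalty <- function(aln, model, pen = aln$pen) {
  pen <- as_penalty_scheme(pen)
  path <- aln$path
  ss <- model$subsequences
  rb <- strsplit(toupper(aln$read$seq), "", fixed = TRUE)[[1]]
  total <- 0
  prev_kind <- 0L; prev_i <- NA_integer_
  for (r in seq_len(nrow(path))) {
    kind <- path[r, "kind"]
    if (kind == 1L) { # match / mismatch
      gb <- substr(ss$seq[path[r, "j"]], path[r, "k"], path[r, "k"])
      total <- total + if (rb[path[r, "i"]] == gb) pen$match else pen$mismatch
    } else if (kind == 2L) { # insertion
      opening <- !(prev_kind == 2L)
      total <- total + if (opening) pen$ins_open else pen$ins_ext
    } else if (kind == 3L) { # deletion: runs share the query position i
      opening <- !(prev_kind == 3L && identical(prev_i, path[r, "i"]))
      total <- total + if (opening) pen$del_open else pen$del_ext
    } else { # clip event (left or right), flat
      total <- total + pen$clip
    }
    prev_kind <- kind; prev_i <- path[r, "i"]
  }
  total
}
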