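#' Alignment penalty scheme
#'
#' Bundle of the penalties used by the realignment dynamic program.  The
#' total penalty of an alignment is minimized, so the match penalty is
#' normally negative and acts as a reward.  Defaults equal the BWA-MEM
#' scoring defaults (match -1, mismatch 4, gap open 6, gap extend 1,
#' clip 5); `str_del_open` is the lowered deletion-open penalty applied to
#' the reference STR region during the reference-projection pass.
#'
#' @param match Match penalty per base (default -1, i.e. a reward).
#' @param mismatch Mismatch penalty per base (> match).
#' @param ins_open,ins_ext Insertion open/extension penalties (>= 0).
#' @param del_open,del_ext Deletion open/extension penalties (>= 0).
#' @param clip Flat penalty charged once per clip event (left or right),
#'   independent of clip length.
#' @param str_del_open Deletion-open penalty for the reference STR region in
#'   the second (projection) pass (default 4).
#' @return An object of class `penalty_scheme` (a named list).
#' @examples
#' penalty_scheme()
#' penalty_scheme(mismatch = 6, clip = 10)
#' @export
penalty_scheme <- function(match = -1, mismatch = 4, ins_open = 6, ins_ext = 1,
                           del_open = 6, del_ext = 1, clip = 5,
                           str_del_open = 4) {
  stopifnot(mismatch > match, ins_open >= 0, ins_ext >= 0,
            del_open >= 0, del_ext >= 0, clip >= 0, str_del_open >= 0)
  structure(list(match = match, mismatch = mismatch,
                 ins_open = ins_open, ins_ext = ins_ext,
                 del_open = del_open, del_ext = del_ext,
                 clip = clip, str_del_open = str_del_open),
            class = "penalty_scheme")
}

#' @export
print.penalty_scheme <- function(x, ...) {
  cat("Penalty scheme (minimized; match < 0 rewards):\n")
  cat(sprintf("  match %g, mismatch %g, ins %g/%g, del %g/%g, clip %g, STR del open %g\n",
              x$match, x$mismatch, x$ins_open, x$ins_ext,
              x$del_open, x$del_ext, x$clip, x$str_del_open))
  invisible(x)
}

as_penalty_scheme <- function(pen) {
  if (inherits(pen, "penalty_scheme")) return(pen)
  do.call(penalty_scheme, as.list(pen))
}
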