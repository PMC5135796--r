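# Evaluation statistics for STR call sets: call rate, RMSE with
# NA-to-reference substitution, and Mendelian trio consistency.

period_strata <- function(period) {
  factor(period, levels = 1:6)
}

#' Call rate of an STR call set
#'
#' Fraction of regions with a non-NA size estimate, stratified by repeat
#' period (1..6) and overall.
#'
#' @param calls Data frame with columns `period` and `a1` (NA = no call).
#' @return Data frame: `period` ("1".."6", "total"), `n`, `called`,
#'   `call_rate`.
#' @export
call_rate <- function(calls) {
  stopifnot(nrow(calls) > 0)
  called <- !is.na(calls$a1)
  per <- period_strata(calls$period)
  n <- tabulate(per, 6L)
  k <- tabulate(per[called], 6L)
  data.frame(period = c(as.character(1:6), "total"),
             n = c(n, nrow(calls)),
             called = c(k, sum(called)),
             call_rate = c(ifelse(n > 0, k / n, NA_real_),
                           sum(called) / nrow(calls)),
             stringsAsFactors = FALSE)
}

#' RMSE between estimated and true STR sizes
#'
#' Root mean squared error in bp between called and true diploid tract
#' sizes, per period and overall.  NA calls are replaced by the reference
#' tract size before differencing.  With `pairing = "allele"` (default) the
#' two estimated alleles are paired with the two true alleles at minimum
#' total squared error and per-allele differences are pooled; with
#' `pairing = "total"` the summed diploid sizes are compared per region.
#'
#' @param calls Data frame with `chrom`, `start`, `end`, `period`,
#'   `ref_size`, `a1`, `a2`.
#' @param truth Data frame with the same keys and true `a1`, `a2`.
#' @param pairing "allele" or "total".
#' @return Data frame: `period`, `n`, `rmse`.
#' @export
size_rmse <- function(calls, truth, pairing = c("allele", "total")) {
  pairing <- match.arg(pairing)
  key <- function(d) paste(d$chrom, d$start, d$end)
  m <- match(key(calls), key(truth))
  if (anyNA(m)) stop("calls contain regions absent from truth")
  truth <- truth[m, , drop = FALSE]
  e1 <- ifelse(is.na(calls$a1), calls$ref_size, calls$a1)
  e2 <- ifelse(is.na(calls$a2), calls$ref_size, calls$a2)
  per <- period_strata(calls$period)
  if (pairing == "allele") {
    d_same <- (e1 - truth$a1)^2 + (e2 - truth$a2)^2
    d_swap <- (e1 - truth$a2)^2 + (e2 - truth$a1)^2
    sq <- pmin(d_same, d_swap) # two squared errors per region
    n_all <- 2L
  } else {
    sq <- ((e1 + e2) - (truth$a1 + truth$a2))^2
    n_all <- 1L
  }
  agg <- function(sel) {
    if (!any(sel)) return(c(n = 0L, rmse = NA_real_))
    c(n = sum(sel), rmse = sqrt(sum(sq[sel]) / (n_all * sum(sel))))
  }
  rows <- lapply(1:6, function(p) agg(per == p))
  tot <- agg(rep(TRUE, length(sq)))
  out <- do.call(rbind, c(rows, list(tot)))
  data.frame(period = c(as.character(1:6), "total"),
             n = as.integer(out[, "n"]), rmse = out[, "rmse"],
             stringsAsFactors = FALSE)
}

#' Mendelian consistency of trio STR calls
#'
#' For every region where the child call is non-NA, the child diploid call
#' (a, b) is consistent when one allele occurs among one parent's called
#' sizes and the other among the other parent's (either assignment).  A
#' parent with an NA call leaves that transmission side unconstrained.
#'
#' @param child,mother,father Call set data frames (`chrom`, `start`, `end`,
#'   `period`, `a1`, `a2`).
#' @return Data frame: `period`, `n_called`, `consistent`, `inconsistent`.
#' @export
mendelian_consistency <- function(child, mother, father) {
  key <- function(d) paste(d$chrom, d$start, d$end)
  mm <- match(key(child), key(mother))
  mf <- match(key(child), key(father))
  if (anyNA(mm) || anyNA(mf)) stop("trio call sets cover different regions")
  mother <- mother[mm, , drop = FALSE]
  father <- father[mf, , drop = FALSE]
  called <- !is.na(child$a1)
  from_parent <- function(allele, p1, p2) {
    is.na(p1) | allele == p1 | allele == p2
  }
  cons <- (from_parent(child$a1, mother$a1, mother$a2) &
             from_parent(child$a2, father$a1, father$a2)) |
    (from_parent(child$a2, mother$a1, mother$a2) &
       from_parent(child$a1, father$a1, father$a2))
  per <- period_strata(child$period)
  n <- tabulate(per[called], 6L)
  k <- tabulate(per[called & cons], 6L)
  data.frame(period = c(as.character(1:6), "total"),
             n_called = c(n, sum(called)),
             consistent = c(k, sum(called & cons)),
             inconsistent = c(n - k, sum(called) - sum(called & cons)),
             stringsAsFactors = FALSE)
}
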