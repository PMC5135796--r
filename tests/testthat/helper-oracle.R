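# Independent oracle for the realignment engine, used on tiny instances.
#
# The model's alignment space is characterized by (i) a choice of copy
# number for every reusable subsequence (zero allowed), (ii) an optional
# left/right clip split of the read, and (iii) a textbook affine-gap fitting
# alignment of the remaining read against the expanded target, annotated so
# that gap runs never cross a subsequence boundary, deletions open only from
# a match in the same block, and no alignment begins with an insertion.
# The oracle minimizes over (i)-(iii) explicitly; it shares no code or data
# layout with the package engine.

# Affine fitting alignment of query chars qc against target chars tc with
# per-position block ids.  Free target prefix/suffix; leading insertions
# forbidden.  Returns the best terminal penalty and, per query row, the best
# match-state value (for right-clip continuation).
oracle_gotoh <- function(qc, tc, block, pen) {
  n <- length(qc); T <- length(tc)
  if (T == 0L) return(list(best = Inf, rowminM = rep(Inf, n)))
  bs <- which(c(TRUE, block[-1] != block[-T])) # block start indices
  be <- c(bs[-1] - 1L, T)
  Hp <- rep(0, T + 1); Ep <- rep(Inf, T + 1); Fp <- rep(Inf, T + 1)
  rowminM <- rep(Inf, n)
  best_end <- Inf
  for (i in seq_len(n)) {
    sub <- ifelse(qc[i] == tc, pen$match, pen$mismatch)
    diag <- pmin(Hp[1:T], Ep[1:T], Fp[1:T])
    H <- c(Inf, diag + sub)
    E <- if (i >= 2) pmin(Hp + pen$ins_open, Ep + pen$ins_ext)
         else rep(Inf, T + 1)
    F <- rep(Inf, T + 1)
    Hc <- H[-1] # H at target positions 1..T
    for (b in seq_along(bs)) {
      lo <- bs[b]; hi <- be[b]
      if (hi > lo) {
        v <- lo:(hi - 1L)
        h <- Hc[v] + pen$del_open - (v + 1) * pen$del_ext
        cm <- cummin(h)
        tpos <- (lo + 1L):hi
        F[tpos + 1L] <- pen$del_ext * tpos + cm
      }
    }
    rowminM[i] <- min(Hc)
    Hp <- H; Ep <- E; Fp <- F
  }
  list(best = min(Hp, Ep), rowminM = rowminM)
}

# Minimum penalty over the model's full alignment space.  subseqs: character
# vector; repflag: logical.  cap: maximum copies per reusable subsequence.
oracle_penalty <- function(read, subseqs, repflag, pen = penalty_scheme(),
                           clip = TRUE, cap = NULL) {
  rb <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(rb)
  ridx <- which(repflag)
  caps <- lapply(ridx, function(j) {
    if (is.null(cap)) 0:(ceiling(n / nchar(subseqs[j])) + 1L) else 0:cap
  })
  combos <- if (length(ridx)) expand.grid(caps) else data.frame(row.names = 1)
  best <- Inf
  for (ci in seq_len(nrow(combos))) {
    tc <- character(0); block <- integer(0)
    for (j in seq_along(subseqs)) {
      s <- if (repflag[j])
        strrep(subseqs[j], combos[ci, match(j, ridx)])
      else subseqs[j]
      if (nchar(s) == 0L) next
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      tc <- c(tc, ch); block <- c(block, rep(j, length(ch)))
    }
    if (length(tc) == 0L) next
    amax <- if (clip) n - 1L else 0L
    for (a in 0:amax) {
      g <- oracle_gotoh(rb[(a + 1L):n], tc, block, pen)
      base <- if (a > 0L) pen$clip else 0
      best <- min(best, base + g$best)
      if (clip && (n - a) >= 2L) {
        rc <- pen$clip + min(g$rowminM[seq_len(n - a - 1L)])
        best <- min(best, base + rc)
      }
    }
  }
  best
}

# Random tiny instance generator for oracle comparisons: model total length
# <= 12 with at most one reusable unit of length <= 3, read length <= 8.
random_tiny_instance <- function() {
  alphabet <- c("A", "C", "G", "T")
  layout <- sample(c("flank", "f-u-f", "u", "f-u", "u-f"), 1,
                   prob = c(.15, .4, .15, .15, .15))
  rnd <- function(k) paste(sample(alphabet, k, replace = TRUE), collapse = "")
  ulen <- sample(1:3, 1)
  fl <- function() rnd(sample(1:5, 1))
  parts <- switch(layout,
    flank = list(seq = fl(), rep = FALSE),
    "f-u-f" = list(seq = c(fl(), rnd(ulen), fl()), rep = c(FALSE, TRUE, FALSE)),
    u = list(seq = rnd(ulen), rep = TRUE),
    "f-u" = list(seq = c(fl(), rnd(ulen)), rep = c(FALSE, TRUE)),
    "u-f" = list(seq = c(rnd(ulen), fl()), rep = c(TRUE, FALSE)))
  seqs <- parts$seq
  repf <- parts$rep
  while (sum(nchar(seqs)) > 12) { # trim a flank to fit the size bound
    j <- which(!repf & nchar(seqs) > 1)[1]
    if (is.na(j)) break
    seqs[j] <- substr(seqs[j], 1, nchar(seqs[j]) - 1)
  }
  nR <- sample(1:8, 1)
  # bias reads toward model-derived content (repeat copies with occasional
  # point changes) half the time, otherwise fully random
  read <- if (stats::runif(1) < 0.5) {
    tract <- paste(mapply(function(s, rf) if (rf) strrep(s, sample(0:3, 1)) else s,
                          seqs, repf), collapse = "")
    if (nchar(tract) < nR) tract <- paste0(tract, rnd(nR))
    off <- sample.int(max(1L, nchar(tract) - nR + 1L), 1)
    r <- substr(tract, off, off + nR - 1L)
    if (stats::runif(1) < 0.4) { # mutate one base
      p <- sample.int(nchar(r), 1)
      substr(r, p, p) <- sample(alphabet, 1)
    }
    r
  } else rnd(nR)
  if (nchar(read) < nR) read <- paste0(read, rnd(nR - nchar(read)))
  list(read = read, seqs = seqs, repflag = repf)
}

# In-memory genome model over arbitrary subsequences (tests only).
toy_model <- function(seqs, repflag, chrom = "chrT") {
  lens <- nchar(seqs)
  ends <- cumsum(lens); starts <- ends - lens
  regs <- NULL
  if (any(repflag)) {
    ri <- which(repflag)
    regs <- str_regions(chrom, starts[ri], pmax(ends[ri], starts[ri] + lens[ri]),
                        lens[ri], seqs[ri])
  }
  structure(list(
    chrom = chrom,
    window = c(start = 0L, end = sum(lens)),
    regions = regs,
    subsequences = data.frame(
      seq = seqs, repeat_flag = repflag, ref_start = starts, ref_end = ends,
      origin = ifelse(repflag, "repeat_unit", "flank"),
      region_idx = ifelse(repflag, cumsum(repflag), NA_integer_),
      stringsAsFactors = FALSE)),
    class = "genome_model")
}
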