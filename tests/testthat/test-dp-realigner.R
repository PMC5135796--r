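pen <- penalty_scheme()

test_that("single-base initialization penalties are exact", {
  expect_equal(realign("A", toy_model("A", FALSE), pen)$penalty, -1)
  expect_equal(realign("C", toy_model("A", FALSE), pen)$penalty, 4)
})

test_that("cyclic reuse of a repeat unit scores consecutive copies", {
  um <- toy_model("AC", TRUE)
  expect_equal(realign("ACAC", um, pen)$penalty, -4)
  expect_equal(realign("ACACAC", um, pen)$penalty, -6)
  expect_equal(realign("AC", toy_model("AC", FALSE), pen)$penalty, -2)
  expect_equal(realign("AG", toy_model("AC", FALSE), pen)$penalty, 3)
})

test_that("zero-copy traversal of repeat subsequences is free", {
  zm <- toy_model(c("TT", "AC", "GG"), c(FALSE, TRUE, FALSE))
  expect_equal(realign("TTGG", zm, pen)$penalty, -4)
  expect_equal(realign("TTACACGG", zm, pen)$penalty, -8)
})

test_that("affine gaps charge open plus per-base extension", {
  # flanking anchors force the interior gap (no cheaper mismatch slippage)
  m <- toy_model("ACGTACGTAC", FALSE)
  expect_equal(realign("ACGTNACGTAC", m, pen, clip = FALSE)$penalty,
               -10 + pen$ins_open)
  expect_equal(realign("ACGTNNACGTAC", m, pen, clip = FALSE)$penalty,
               -10 + pen$ins_open + pen$ins_ext)
  expect_equal(realign("ACGTCGTAC", m, pen, clip = FALSE)$penalty,
               -9 + pen$del_open)
  expect_equal(realign("ACGTGTAC", m, pen, clip = FALSE)$penalty,
               -8 + pen$del_open + pen$del_ext)
})

test_that("clipping is flat per event and independent of clip length", {
  cm <- toy_model("ACGTACGT", FALSE)
  one <- realign("NACGTACGT", cm, pen)   # 1 junk base
  many <- realign("NNNNNACGTACGT", cm, pen)
  expect_equal(one$penalty, -8 + pen$clip)
  expect_equal(many$penalty, -8 + pen$clip)
  expect_equal(many$left_clip, 5L)
  # clip beats mismatches for garbage prefixes
  expect_equal(realign("NNAC", toy_model("AC", FALSE), pen)$penalty, 3)
})

test_that("rotating multi-deletions stay below one unit length", {
  # forced case: two ACG copies with a 2 bp loss spanning the copy boundary
  # (read tract ACCG = copy phases 1,2 | 2,3 with phases 3,1 deleted in
  # between) — the deletion rotates from unit tail to head
  m <- toy_model(c("TTTT", "ACG", "GGGG"), c(FALSE, TRUE, FALSE))
  a <- realign("TTTTACCGGGGG", m, pen)
  expect_equal(a$penalty, -8 + (-4 + pen$del_open + pen$del_ext))
  d <- a$path[a$path[, "kind"] == 3L, , drop = FALSE]
  expect_equal(nrow(d), 2L)
  expect_equal(unname(d[, "k"]), c(3L, 1L))
  expect_equal(unique(d[, "l"]), 2L)
  expect_lt(2L, nchar("ACG")) # the bound itself: run shorter than the unit

  set.seed(21)
  for (t in 1:200) {
    inst <- random_tiny_instance()
    m <- toy_model(inst$seqs, inst$repflag)
    a <- realign(inst$read, m, pen)
    path <- a$path
    d <- path[path[, "kind"] == 3L, , drop = FALSE]
    if (nrow(d) == 0L) next
    runs <- split(seq_len(nrow(d)), cumsum(c(TRUE, diff(d[, "i"]) != 0L |
                                               diff(d[, "j"]) != 0L)))
    for (rr in runs) {
      j <- d[rr[1], "j"]
      if (m$subsequences$repeat_flag[j])
        expect_lt(length(rr), nchar(m$subsequences$seq[j]))
    }
  }
})

test_that("every path conserves the read bases", {
  set.seed(22)
  for (t in 1:200) {
    inst <- random_tiny_instance()
    a <- realign(inst$read, toy_model(inst$seqs, inst$repflag), pen)
    k <- a$path[, "kind"]
    expect_equal(sum(k == 1L) + sum(k == 2L) + a$left_clip + a$right_clip,
                 nchar(inst$read))
  }
})

test_that("re-scoring a traceback reproduces the dynamic program's penalty", {
  set.seed(23)
  for (t in 1:200) {
    inst <- random_tiny_instance()
    m <- toy_model(inst$seqs, inst$repflag)
    a <- realign(inst$read, m, pen)
    expect_equal(alignment_penalty(a, m, pen), a$penalty)
  }
  # hand-built checks at defaults
  fm <- toy_model("ACGTT", FALSE)
  a <- realign("ACG", fm, pen, clip = FALSE)
  expect_equal(alignment_penalty(a, fm), -3)
})

test_that("real-valued penalties are accepted", {
  p2 <- penalty_scheme(match = -0.5, mismatch = 3.25, ins_open = 4.5,
                       ins_ext = 0.75, del_open = 4.5, del_ext = 0.75,
                       clip = 3.5)
  m <- toy_model(c("TT", "AC", "GG"), c(FALSE, TRUE, FALSE))
  a <- realign("TTACACGG", m, p2)
  expect_equal(a$penalty, -4)
  expect_equal(alignment_penalty(a, m, p2), a$penalty)
})

test_that("state updates scale linearly in read length at fixed model", {
  m <- toy_model(c(strrep("ACGT", 10), "GAT", strrep("TTCA", 10)),
                 c(FALSE, TRUE, FALSE))
  r1 <- realign(strrep("GAT", 10), m, pen)       # |R| = 30
  r2 <- realign(strrep("GAT", 20), m, pen)       # |R| = 60
  ratio <- r2$n_updates / r1$n_updates
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
  # per-position updates bounded by c * (sum |G| + sum_{B=1} |G|^2)
  sizes <- nchar(m$subsequences$seq)
  bound <- sum(sizes) + sum(sizes[m$subsequences$repeat_flag]^2)
  expect_lt(r2$n_updates / 60, 10 * bound)
})

test_that("tie-breaking makes tracebacks deterministic", {
  m <- toy_model(c("TT", "AC", "GG"), c(FALSE, TRUE, FALSE))
  a <- realign("TTACACGG", m, pen)
  b <- realign("TTACACGG", m, pen)
  expect_identical(a$path, b$path)
})

test_that("degenerate inputs are rejected", {
  m <- toy_model("ACGT", FALSE)
  expect_error(realign("", m, pen), "at least one base")
})
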