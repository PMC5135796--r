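mk_calls <- function(n, period = 2L, a1 = 20L, a2 = 24L, ref_size = 20L,
                     start = NULL) {
  if (is.null(start)) start <- seq_len(n) * 1000L
  data.frame(chrom = "chr1", start = start, end = start + ref_size,
             period = period, ref_size = ref_size,
             a1 = a1, a2 = a2, stringsAsFactors = FALSE)
}

test_that("call rate counts non-NA calls per period and overall", {
  calls <- mk_calls(10)
  calls$a1[1] <- NA; calls$a2[1] <- NA
  cr <- call_rate(calls)
  expect_equal(cr$call_rate[cr$period == "total"], 0.9)
  allna <- mk_calls(4); allna$a1 <- NA; allna$a2 <- NA
  expect_equal(call_rate(allna)$call_rate[7], 0)
  # partition: per-period numerators sum to the total numerator
  mixed <- mk_calls(12, period = rep(1:6, 2))
  mixed$a1[c(2, 5)] <- NA
  cr <- call_rate(mixed)
  expect_equal(sum(cr$called[1:6]), cr$called[7])
  expect_true(all(cr$call_rate >= 0 & cr$call_rate <= 1, na.rm = TRUE))
})

test_that("RMSE pools min-cost paired allele errors, substituting NA by reference", {
  truth <- mk_calls(2, a1 = c(10L, 30L), a2 = c(20L, 34L))
  exact <- truth
  expect_equal(size_rmse(exact, truth)$rmse[7], 0)
  # per-allele errors (3,4) and (0,0): RMSE = sqrt((9+16)/4) = 2.5
  est <- truth; est$a1 <- truth$a1 + c(3L, 0L); est$a2 <- truth$a2 + c(4L, 0L)
  expect_equal(size_rmse(est, truth)$rmse[7], 2.5)
  # allele pairing is order-invariant
  swapped <- est; swapped$a1 <- est$a2; swapped$a2 <- est$a1
  expect_equal(size_rmse(swapped, truth)$rmse[7], 2.5)
  # NA call with truth equal to reference contributes zero
  t2 <- mk_calls(1, a1 = 20L, a2 = 20L, ref_size = 20L)
  e2 <- t2; e2$a1 <- NA; e2$a2 <- NA
  expect_equal(size_rmse(e2, t2)$rmse[7], 0)
  # NA substitution uses the reference size
  t3 <- mk_calls(1, a1 = 26L, a2 = 20L, ref_size = 20L)
  e3 <- t3; e3$a1 <- NA; e3$a2 <- NA
  expect_equal(size_rmse(e3, t3)$rmse[7], sqrt(36 / 2))
  # region order invariance
  t4 <- mk_calls(6, a1 = 10L + 2L * (1:6), a2 = 30L)
  e4 <- t4; e4$a1 <- e4$a1 + 1L
  perm <- sample(6)
  expect_equal(size_rmse(e4[perm, ], t4)$rmse[7], size_rmse(e4, t4)$rmse[7])
  # summed-diploid alternative
  expect_equal(size_rmse(est, truth, pairing = "total")$rmse[7],
               sqrt(49 / 2))
  expect_error(size_rmse(mk_calls(3), truth), "absent")
})

# Brute-force check for the NA-parent rule: a child is consistent with an NA
# parent iff some completion of that parent makes the trio consistent.
consistent_brute <- function(child, mother, father, sizes = seq(4, 40, 4)) {
  completions <- function(p) {
    if (!is.na(p[1])) return(list(p))
    unlist(lapply(sizes, function(x) lapply(sizes, function(y) c(x, y))),
           recursive = FALSE)
  }
  for (mo in completions(mother)) for (fa in completions(father)) {
    ok <- (child[1] %in% mo && child[2] %in% fa) ||
      (child[2] %in% mo && child[1] %in% fa)
    if (ok) return(TRUE)
  }
  FALSE
}

test_that("Mendelian consistency handles direct, impossible and NA-parent cases", {
  trio <- function(c12, m12, f12) {
    child <- mk_calls(1, a1 = c12[1], a2 = c12[2])
    mother <- mk_calls(1, a1 = m12[1], a2 = m12[2])
    father <- mk_calls(1, a1 = f12[1], a2 = f12[2])
    mendelian_consistency(child, mother, father)$consistent[7] == 1L
  }
  expect_true(trio(c(20, 24), c(20, 20), c(24, 28)))
  expect_false(trio(c(20, 24), c(28, 28), c(28, 28)))
  # NA parent: unconstrained, matches enumeration over completions
  expect_true(trio(c(20, 24), c(NA, NA), c(24, 28)))
  expect_equal(trio(c(20, 24), c(NA, NA), c(24, 28)),
               consistent_brute(c(20, 24), c(NA, NA), c(24, 28)))
  expect_equal(trio(c(20, 24), c(NA, NA), c(28, 28)),
               consistent_brute(c(20, 24), c(NA, NA), c(28, 28)))
  # crossed assignment counts
  expect_true(trio(c(20, 24), c(24, 28), c(20, 16)))
})

test_that("consistent and inconsistent counts partition the called regions", {
  set.seed(51)
  n <- 60L
  start <- seq_len(n) * 500L
  period <- rep(1:6, 10)
  mo <- mk_calls(n, period = period, start = start,
                 a1 = 4L * sample(3:8, n, TRUE), a2 = 4L * sample(3:8, n, TRUE))
  fa <- mk_calls(n, period = period, start = start,
                 a1 = 4L * sample(3:8, n, TRUE), a2 = 4L * sample(3:8, n, TRUE))
  # faithful transmission: one allele from each parent
  pick <- function(p) ifelse(stats::runif(n) < 0.5, p$a1, p$a2)
  ch <- mk_calls(n, period = period, start = start,
                 a1 = pick(mo), a2 = pick(fa))
  ch$a1[sample(n, 10)] <- NA
  ch$a2[is.na(ch$a1)] <- NA
  mc <- mendelian_consistency(ch, mo, fa)
  expect_equal(mc$consistent[7] + mc$inconsistent[7], sum(!is.na(ch$a1)))
  expect_equal(sum(mc$n_called[1:6]), mc$n_called[7])
  # with faithful transmission and full parent calls, nothing is inconsistent
  expect_equal(mc$inconsistent[7], 0L)
})
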