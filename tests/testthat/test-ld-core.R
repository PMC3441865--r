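# LD statistics on phased haplotype columns.

test_that("allele frequencies count haplotypes, resolve ties to the reference allele, and flag monomorphic columns", {
  f <- allele_frequencies(c(0L, 0L, 0L, 1L))
  expect_equal(f$p_major, 0.75)
  expect_equal(f$major_allele, 0L)
  expect_false(f$monomorphic)

  tie <- allele_frequencies(c(0L, 1L, 0L, 1L))
  expect_equal(tie$major_allele, 0L)
  expect_equal(tie$p_major, 0.5)

  mono <- allele_frequencies(c(1L, 1L, 1L, 1L))
  expect_true(mono$monomorphic)

  expect_error(allele_frequencies(c(NA_integer_, NA_integer_)), "missing")

  # missing entries drop out of the counts
  fm <- allele_frequencies(c(0L, 0L, NA_integer_, 1L))
  expect_equal(fm$n_used, 3L)
  expect_equal(fm$p_major, 2 / 3)
})

test_that("joint haplotype frequency uses pairwise-complete deletion", {
  hf <- haplotype_freq_ab(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  expect_equal(hf$p_ab, 0.5)
  expect_equal(hf$n_used, 4L)

  hf2 <- haplotype_freq_ab(c(0L, 0L, 1L, 1L), c(0L, NA_integer_, 1L, 1L))
  expect_equal(hf2$n_used, 3L)

  cc <- cols_from_counts(4L, 1L, 1L, 4L)
  hf3 <- haplotype_freq_ab(cc$x, cc$y)
  expect_equal(hf3$p_ab, 0.4)
})

test_that("worked haplotype-count configurations give the expected D, D' and r2 exactly", {
  # counts AB/Ab/aB/ab = 4/1/1/4 over 10 haplotypes
  cc <- cols_from_counts(4L, 1L, 1L, 4L)
  st <- compute_ld(cc$x, cc$y)
  expect_equal(st$d, 0.15)
  expect_equal(st$r2, 0.36)
  expect_equal(st$d_prime, 0.6)

  # mirrored counts flip the sign of D and D'
  cm <- cols_from_counts(1L, 4L, 4L, 1L)
  sm <- compute_ld(cm$x, cm$y)
  expect_equal(sm$d, -0.15)
  expect_equal(sm$r2, 0.36)
  expect_equal(sm$d_prime, -0.6)

  # duplicated columns are in complete LD
  x <- rep(c(0L, 1L, 0L, 0L, 1L), 4L)
  sd <- compute_ld(x, x)
  expect_equal(sd$r2, 1)
  expect_equal(sd$d_prime, 1)

  # independent counts 3/3/1/1: D = 0, and D' is defined as 0 there
  ci <- cols_from_counts(3L, 3L, 1L, 1L)
  si <- compute_ld(ci$x, ci$y)
  expect_equal(si$d, 0)
  expect_equal(si$r2, 0)
  expect_equal(si$d_prime, 0)
})

test_that("compute_ld flags monomorphic and low-n pairs instead of returning numbers", {
  mono <- compute_ld(rep(1L, 10), rep(c(0L, 1L), 5))
  expect_equal(mono$status, "MONOMORPHIC")
  expect_true(is.na(mono$r2))

  # pairwise deletion can make a locus monomorphic
  x <- c(0L, 1L, 1L, 1L)
  y <- c(NA_integer_, 0L, 1L, 0L)
  expect_equal(compute_ld(x, y)$status, "MONOMORPHIC")

  low <- compute_ld(c(0L, 1L, NA, NA), c(NA, NA, 0L, 1L),
                    min_haplotypes = 2L)
  expect_equal(low$status, "LOW_N")

  skipped <- compute_ld(rep(c(0L, 1L), 10), rep(c(0L, 1L), 10),
                        min_haplotypes = 40L)
  expect_equal(skipped$status, "LOW_N")
})

test_that("compute_ld agrees with the brute-force contingency-table oracle on random columns", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(20:100, 1L)
    cc <- random_cols(n, miss_rate = if (rep %% 4 == 0) 0.1 else 0)
    st <- compute_ld(cc$x, cc$y)
    br <- ld_brute(cc$x, cc$y)
    expect_equal(st$d, br$d, tolerance = 1e-12)
    expect_equal(st$d_prime, br$d_prime, tolerance = 1e-12)
    expect_equal(st$r2, br$r2, tolerance = 1e-12)
    expect_equal(st$n_used, br$n_used)
  }
})

test_that("r2 is symmetric, invariant to allele relabeling, and D negates under a flip", {
  set.seed(7)
  for (rep in 1:50) {
    cc <- random_cols(sample(20:60, 1L))
    a <- compute_ld(cc$x, cc$y)
    b <- compute_ld(cc$y, cc$x)
    expect_identical(a$r2, b$r2)
    expect_identical(abs(a$d_prime), abs(b$d_prime))

    # relabeling 0<->1 at a locus never changes r2; under the
    # major-allele convention the major tracks the physical allele, so
    # |D| is preserved as well
    flipped <- compute_ld(1L - cc$x, cc$y)
    expect_equal(flipped$r2, a$r2, tolerance = 1e-15)
    expect_equal(abs(flipped$d), abs(a$d), tolerance = 1e-15)
  }

  # at a frequency-0.5 tie the major designation is pinned to the coded
  # reference allele, so relabeling negates D there
  cc <- cols_from_counts(4L, 1L, 1L, 4L)
  a <- compute_ld(cc$x, cc$y)
  flipped <- compute_ld(1L - cc$x, cc$y)
  expect_equal(flipped$d, -a$d)
  expect_equal(flipped$r2, a$r2)
})

test_that("r2 reaches 1 exactly when two concordant haplotype classes remain", {
  # two nonzero concordant classes -> complete LD
  conc <- cols_from_counts(6L, 0L, 0L, 4L)
  expect_equal(compute_ld(conc$x, conc$y)$r2, 1)
  anti <- cols_from_counts(0L, 6L, 4L, 0L)
  expect_equal(compute_ld(anti$x, anti$y)$r2, 1)

  # a third occupied class breaks completeness
  three <- cols_from_counts(5L, 1L, 0L, 4L)
  expect_lt(compute_ld(three$x, three$y)$r2, 1)

  # exhaustive check over small panels: r2 == 1 iff exactly two occupied
  # classes and they are concordant (both loci still polymorphic)
  for (ab in 0:4) for (a_b in 0:4) for (ab2 in 0:4) for (abab in 0:4) {
    n <- ab + a_b + ab2 + abab
    if (n < 4) next
    if ((ab + a_b) %in% c(0L, n) || (ab + ab2) %in% c(0L, n)) next
    cc <- cols_from_counts(ab, a_b, ab2, abab)
    st <- compute_ld(cc$x, cc$y)
    two_conc <- (a_b == 0 && ab2 == 0 && ab > 0 && abab > 0) ||
      (ab == 0 && abab == 0 && a_b > 0 && ab2 > 0)
    expect_equal(abs(st$r2 - 1) < 1e-9, two_conc)
  }
})

test_that("tidy and glance return one-row summaries of an LD fit", {
  cc <- cols_from_counts(4L, 1L, 1L, 4L)
  st <- compute_ld(cc$x, cc$y)
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$r2, 0.36)
  expect_equal(glance(st)$status, "OK")
})
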