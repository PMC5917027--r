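test_that("haplotype calling groups identical and compatible sequences", {
  aln <- mt_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  tab <- call_haplotypes(aln)
  expect_equal(tab$H, 1L)
  expect_equal(tab$counts, 4L)
  expect_equal(tab$labels, "a")

  aln <- mt_alignment(c(p = "AA", q = "AT", r = "AA"))
  tab <- call_haplotypes(aln)
  expect_equal(tab$H, 2L)
  expect_equal(sort(tab$counts), c(1L, 2L))

  # AN matches AA on resolved sites under the compatible rule
  fx <- toy_fixtures()$hap_missing
  tab <- call_haplotypes(fx$alignment)
  expect_equal(tab$H, fx$truth$H_compatible)
  # strict mode drops the N column for everyone: AA == AN on column 1
  tabs <- call_haplotypes(fx$alignment, mode = "strict")
  expect_equal(tabs$H, 2L)
  # counts always sum to n
  expect_equal(sum(tab$counts), aln_nseq(fx$alignment))
})

test_that("haplotype diversity matches the closed form and its bounds", {
  expect_equal(haplotype_diversity(c(4)), 0)
  expect_equal(haplotype_diversity(rep(1, 7)), 1)
  expect_equal(haplotype_diversity(c(2, 1, 1)), 0.83333, tolerance = 1e-4)
  expect_error(haplotype_diversity(c(1)), "n >= 2")
  set.seed(21)
  for (i in 1:10) {
    cnt <- sample(1:5, sample(2:6, 1), replace = TRUE)
    hd <- haplotype_diversity(cnt)
    expect_gte(hd, 0)
    expect_lte(hd, 1)
  }
  # Hd = 0 iff a single haplotype
  expect_gt(haplotype_diversity(c(9, 1)), 0)
})

test_that("pairwise differences match brute-force enumeration", {
  aln <- mt_alignment(c(x = "AAAAAAAAAA", y = "AAAAAAAAAT", z = "AAAAAAAATT"))
  pw <- pairwise_diff_stats(aln)
  expect_equal(pw$k_bar, 4 / 3)
  expect_equal(pw$pi, 4 / 30)
  expect_equal(pairwise_diff_stats(mt_alignment(c(u = "ACGT", v = "ACGT")))$k_bar, 0)

  set.seed(31)
  for (i in 1:6) {
    aln <- random_alignment(8, 30, missing_frac = ifelse(i %% 2, 0, 0.15))
    pw <- pairwise_diff_stats(aln)
    or <- oracle_pairwise(aln)
    expect_equal(pw$k_bar, or$k_bar, tolerance = 1e-12)
    expect_equal(pw$pi, or$pi, tolerance = 1e-12)
    expect_equal(pw$S, oracle_S(aln))
    # row permutation leaves the statistics unchanged
    perm <- aln_subset_for_test(aln, sample(aln_nseq(aln)))
    pwp <- pairwise_diff_stats(perm)
    expect_equal(pwp$k_bar, pw$k_bar)
    expect_equal(pwp$pi, pw$pi)
  }
})

test_that("Tajima's D reproduces the hand-computed fixture and oracle", {
  fx <- toy_fixtures()$tajima_n4
  expect_equal(tajimas_d(fx$alignment), fx$truth$tajima_d, tolerance = 1e-3)
  expect_warning(d <- tajimas_d(toy_fixtures()$mono$alignment), "monomorphic")
  expect_true(is.na(d))
  expect_error(tajimas_d(mt_alignment(c(a = "AT", b = "TA", c = "AA"))), "n >= 4")
  set.seed(41)
  for (i in 1:5) {
    aln <- random_alignment(9, 40, n_hap = 5)
    if (pairwise_diff_stats(aln)$S < 1) next
    expect_equal(tajimas_d(aln), oracle_tajima(aln), tolerance = 1e-12)
  }
})

test_that("Hudson's FST behaves at the fixed, identical and panmictic limits", {
  fx <- toy_fixtures()$fst_fixed
  g <- fx$truth$groups
  A <- aln_subset_for_test(fx$alignment, which(g == "a"))
  B <- aln_subset_for_test(fx$alignment, which(g == "b"))
  expect_equal(hudson_fst(A, B), 1.0)
  # identical composition: the unbiased estimator gives -1/(n-1), not exactly 0
  seqs <- c(rep("ACGTACGT", 6), rep("ACTTACGT", 6))
  ids <- sprintf("s%02d", 1:12)
  big <- mt_alignment(setNames(seqs, ids))
  same <- hudson_fst(aln_subset_for_test(big, 1:6 * 2 - 1),
                     aln_subset_for_test(big, 1:6 * 2))
  expect_equal(same, -1 / (6 - 1), tolerance = 1e-12)
  expect_warning(
    res <- hudson_fst(mt_alignment(c(a = "AA", b = "AA")),
                      mt_alignment(c(c = "AA", d = "AA"))),
    "undefined")
  expect_true(is.na(res))
  # two subsamples of one panmictic pool: mean FST near 0
  set.seed(51)
  vals <- replicate(200, {
    pool <- random_alignment(12, 25, n_hap = 6)
    idx <- sample(12, 6)
    hudson_fst(aln_subset_for_test(pool, idx),
               aln_subset_for_test(pool, setdiff(1:12, idx)))
  })
  expect_lt(abs(mean(vals)), 3 * stats::sd(vals) / sqrt(length(vals)) + 0.02)
})

test_that("private haplotype counts partition the union", {
  A <- call_haplotypes(mt_alignment(c(a1 = "AAAA", a2 = "AATT", a3 = "AAAA")))
  B <- call_haplotypes(mt_alignment(c(b1 = "TTTT")))
  pr <- private_haplotypes(A, B)
  expect_equal(unlist(pr), c(private_a = 2L, private_b = 1L, shared = 0L))
  pr2 <- private_haplotypes(A, A)
  expect_equal(pr2$shared, A$H)
  expect_equal(pr2$private_a + pr2$private_b, 0L)
  # the historical/modern mountain pattern: 4 vs 2 haplotypes, 1 shared
  hist <- mt_alignment(c(h1 = "AAAA", h2 = "AAAT", h3 = "AATT", h4 = "ATTT"))
  mod <- mt_alignment(c(m1 = "AAAA", m2 = "CAAA"))
  pr3 <- private_haplotypes(call_haplotypes(hist), call_haplotypes(mod))
  expect_equal(unlist(pr3), c(private_a = 3L, private_b = 1L, shared = 1L))
})

test_that("diversity panel is internally consistent on random data", {
  set.seed(61)
  aln <- random_alignment(15, 50, n_hap = 7)
  st <- diversity_stats(aln)
  expect_lte(st$H, st$n)
  expect_gte(st$Hd, 0); expect_lte(st$Hd, 1)
  expect_equal(st$pi, st$k_bar / 50)
  groups <- list(g1 = aln, g2 = aln)
  gd <- group_diversity(groups)
  expect_equal(nrow(gd), 2L)
  expect_equal(gd$Hd[1], gd$Hd[2])
})
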