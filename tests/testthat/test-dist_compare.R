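test_that("AF histograms use half-open bins with the last bin closed", {
  h <- histogram_af(c(0.5, 0.5), bin_width = 0.5)
  expect_equal(h$abundances, c(0, 1))  # 0.5 falls in the second bin

  h1 <- histogram_af(0.3, bin_width = 0.025)
  expect_equal(sum(h1$abundances), 1)
  expect_equal(h1$abundances[13], 1)   # [0.3, 0.325)

  centers <- seq(0.0125, by = 0.025, length.out = 40)
  hu <- histogram_af(centers, bin_width = 0.025)
  expect_equal(hu$abundances, rep(1 / 40, 40))

  expect_equal(histogram_af(1.0, 0.025)$abundances[40], 1)  # 1.0 in last bin
  expect_error(histogram_af(numeric()), "empty")
  expect_error(histogram_af(c(0.2, 1.2)), "0, 1")
})

test_that("chain EMD equals the optimal transport cost", {
  mk <- function(a) structure(list(bin_width = 1 / length(a),
                                   abundances = a), class = "af_histogram")
  # mass 1 moved across 2 bins
  expect_equal(emd(mk(c(1, 0, 0)), mk(c(0, 0, 1))), 2)
  expect_equal(emd(mk(c(0.5, 0.25, 0.25)), mk(c(0.5, 0.25, 0.25))), 0)
  # crossing-CDF case: 0.5 from each side to the center, NOT 2
  expect_equal(emd(mk(c(0.5, 0, 0.5)), mk(c(0, 1, 0))), 1)

  # oracle agreement on random pairs, symmetry, triangle inequality
  set.seed(7)
  for (i in seq_len(200)) {
    n <- sample(2:12, 1)
    h1 <- random_histogram(n); h2 <- random_histogram(n)
    d <- emd(h1, h2)
    expect_equal(d, transport_emd_oracle(h1$abundances, h2$abundances),
                 tolerance = 1e-9)
    expect_equal(d, emd(h2, h1))
    h3 <- random_histogram(n)
    expect_lte(emd(h1, h3), d + emd(h2, h3) + 1e-12)
  }
  expect_error(emd(mk(c(1, 0)), mk(c(1, 0, 0))), "share")
})

test_that("KS comparison matches a brute-force ECDF sweep", {
  x <- c(0.1, 0.2, 0.3); y <- c(0.1, 0.2, 0.3, 0.4)
  ks <- ks_compare(x, y)
  pts <- sort(unique(c(x, y)))
  gap <- max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p),
                        numeric(1))))
  expect_equal(ks$D, gap)

  expect_equal(ks_compare(x, x)$D, 0)
  lo <- seq(0.1, 0.2, length.out = 20); hi <- seq(0.4, 0.5, length.out = 20)
  expect_equal(ks_compare(lo, hi)$D, 1)
  expect_error(ks_compare(0.3, x), "at least 2")
})

test_that("KDE absolute-difference behaves like a total-variation distance", {
  x <- runif(100, 0.1, 0.5)
  expect_equal(kde_abs_diff(x, x), 0)
  # fully separated narrow interior clusters approach 2
  a <- rnorm(200, 0.2, 0.003); b <- rnorm(200, 0.7, 0.003)
  expect_gt(kde_abs_diff(a, b, sigma = 0.005), 1.9)
  expect_lte(kde_abs_diff(a, b, sigma = 0.005), 2 + 1e-6)
  # non-negative and symmetric on random pairs
  set.seed(3)
  for (i in 1:5) {
    p <- runif(30, 0, 1); q <- runif(40, 0, 1)
    d <- kde_abs_diff(p, q)
    expect_gte(d, 0)
    expect_equal(d, kde_abs_diff(q, p))
  }
  expect_error(kde_abs_diff(x, x, sigma = 0), "positive")
})

test_that("L2 permutation test is deterministic, calibrated and powered", {
  x <- runif(60, 0.1, 0.5)
  same <- l2_permutation_test(x, x, seed = 5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)  # every permutation ties or exceeds

  r1 <- l2_permutation_test(x, runif(50, 0.1, 0.5), seed = 9)
  r2 <- l2_permutation_test(x, runif(50, 0.1, 0.5), seed = 9)
  expect_true(r1$p >= 0 && r1$p <= 1)

  # well-separated clusters are significant across seeds
  set.seed(11)
  a <- runif(50, 0.1, 0.2); b <- runif(50, 0.4, 0.5)
  ps <- vapply(1:20, function(s)
    l2_permutation_test(a, b, seed = s)$p, numeric(1))
  expect_true(all(ps <= 0.05))

  # same seed, same answer
  expect_identical(l2_permutation_test(a, b, seed = 3),
                   l2_permutation_test(a, b, seed = 3))
  expect_error(l2_permutation_test(a, b, n_perm = 0), "n_perm")
})

test_that("shared-locus AF correlation intersects on chrom:pos:alt", {
  mk <- function(pos, af, alt = "T") variant_calls(
    chrom = "chr1", pos = pos, ref = "A", alt = alt, tumor_af = af,
    normal_af = 0, tumor_depth = 100L, normal_depth = 100L,
    filter_status = "PASS", caller = "mutect")
  a <- mk(c(1L, 2L, 3L, 4L, 5L), c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(shared_af_correlation(a, a), 1)
  b <- mk(c(1L, 2L, 3L, 4L, 5L), c(0.5, 0.4, 0.3, 0.2, 0.1))
  expect_equal(shared_af_correlation(a, b), -1)
  # fewer than 3 shared loci -> NA
  expect_true(is.na(shared_af_correlation(mk(1:2, c(0.1, 0.2)),
                                          mk(1:2, c(0.1, 0.2)))))
  # different alt at same position is not shared
  expect_true(is.na(shared_af_correlation(a, mk(1:5, a$tumor_af, alt = "G"))))
  # jittered duplicates stay tightly correlated
  set.seed(13)
  jit <- a; jit$tumor_af <- pmin(pmax(a$tumor_af + rnorm(5, 0, 0.01), 0), 1)
  expect_gt(shared_af_correlation(a, jit), 0.95)
})

test_that("cohort summary applies the per-pair Bonferroni threshold", {
  set.seed(21)
  ids <- sprintf("S%d", 1:6)
  # pseudo-caller pair differing only by tiny AF jitter: no significance
  base <- lapply(ids, function(i) runif(150, 0.1, 0.5))
  names(base) <- ids
  jit <- lapply(base, function(v) pmin(pmax(v + rnorm(150, 0, 0.01), 0.1), 1))
  cfg <- comparison_config(n_permutations = 20, seed = 2)
  s1 <- cohort_pairwise_summary(list(a = base, b = jit), cfg)
  expect_equal(s1$n_samples, 6)
  expect_equal(s1$bonferroni_threshold, 0.05 / 6)
  expect_equal(s1$fraction_significant, 0)
  expect_lt(s1$median_emd, 2)

  # a pair with strongly shifted distributions: everything significant
  shift <- lapply(base, function(v) pmin(v + 0.3, 0.99))
  s2 <- cohort_pairwise_summary(list(a = base, b = shift), cfg)
  expect_equal(s2$fraction_significant, 1)
  expect_gt(s2$median_emd, s1$median_emd)

  # identical sets: zero distances everywhere
  s3 <- cohort_pairwise_summary(list(a = base, b = base), cfg)
  expect_equal(s3$fraction_significant, 0)
  expect_equal(s3$median_emd, 0)

  expect_error(cohort_pairwise_summary(
    list(a = base, b = setNames(jit, paste0("X", ids))), cfg),
    "no shared samples")
})
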