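test_that("MATH score matches hand computation and is scale invariant", {
  # median 0.3, raw MAD 0.1, scaled 0.14826 -> 49.42
  expect_equal(math_score(c(0.1, 0.2, 0.3, 0.4, 0.5)),
               100 * 1.4826 * 0.1 / 0.3)
  expect_equal(math_score(rep(0.4, 7)), 0)
  # purity scales all AFs by a constant and must not change MATH
  set.seed(17)
  x <- runif(51, 0.1, 0.5)
  for (c_pur in c(0.25, 0.6, 1)) {
    expect_equal(math_score(c_pur * x), math_score(x), tolerance = 1e-12)
  }
  # CCF-style score vectors (values above 1) are scored identically
  expect_equal(math_score(2 * x), math_score(x), tolerance = 1e-12)
  expect_error(math_score(numeric()), "empty")
  expect_error(math_score(c(0, 0, 0)), "median")
})

test_that("AF standard deviation is population-style", {
  expect_equal(af_std(c(0, 1)), 0.5)
  expect_equal(af_std(rep(0.3, 10)), 0)
  expect_true(is.na(af_std(0.4)))
  set.seed(23)
  for (i in 1:20) {
    x <- runif(sample(2:40, 1))
    expect_equal(af_std(x), sqrt(sum((x - mean(x))^2) / length(x)))
  }
})

test_that("CNV std at SNV loci looks up segment means and drops gaps", {
  prof <- cnv_profile("S1", data.frame(
    chrom = "chr1", start = c(1L, 1001L, 3001L), end = c(1000L, 3000L, 6000L),
    segment_mean = c(0, 1, 0.4)))
  loci2 <- data.frame(chrom = "chr1", pos = c(500L, 2000L))
  expect_equal(cnv_std_at_snvs(prof, loci2), 0.5)  # means {0, 1}
  one_seg <- data.frame(chrom = "chr1", pos = c(1100L, 1500L, 2500L))
  expect_equal(cnv_std_at_snvs(prof, one_seg), 0)
  # 5 SNVs over 3 segments, one in a gap: hand-computed population std
  loci5 <- data.frame(chrom = "chr1", pos = c(500L, 900L, 2000L, 4000L, 9000L))
  vals <- c(0, 0, 1, 0.4)
  expect_equal(cnv_std_at_snvs(prof, loci5),
               sqrt(mean((vals - mean(vals))^2)))
  # fewer than 2 covered loci -> NA
  expect_true(is.na(cnv_std_at_snvs(prof, data.frame(chrom = "chr1",
                                                     pos = 9000L))))
})

test_that("whole-genome CNV std is the length-weighted population std", {
  # lengths 1 and 3, means 0 and 1: cbar 0.75, std sqrt(0.1875)
  prof <- cnv_profile("S1", data.frame(
    chrom = "chr1", start = c(1L, 2L), end = c(1L, 4L),
    segment_mean = c(0, 1)))
  expect_equal(wg_cnv_std(prof), sqrt(0.1875))

  single <- cnv_profile("S1", data.frame(chrom = "chr1", start = 1L,
                                         end = 100L, segment_mean = 0.7))
  expect_equal(wg_cnv_std(single), 0)

  # equal lengths reduce to the unweighted population std
  m <- c(-0.4, 0.1, 0.5, 0.2)
  eq <- cnv_profile("S1", data.frame(
    chrom = "chr1", start = c(1L, 101L, 201L, 301L),
    end = c(100L, 200L, 300L, 400L), segment_mean = m))
  expect_equal(wg_cnv_std(eq), sqrt(mean((m - mean(m))^2)))

  # brute-force per-base agreement on small random profiles (<= 10 kb)
  set.seed(29)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    lens <- sample(50:2000, k)
    ends <- cumsum(lens)
    prof <- cnv_profile("S1", data.frame(
      chrom = "chr1", start = c(1L, head(ends, -1) + 1L), end = ends,
      segment_mean = rnorm(k, 0, 0.5)))
    expect_equal(wg_cnv_std(prof), per_base_cnv_std(prof), tolerance = 1e-9)
  }
})

test_that("copy-number filter drops aberrant loci and keeps uncovered ones", {
  prof <- cnv_profile("S1", data.frame(
    chrom = "chr1", start = c(1L, 1001L, 2001L), end = c(1000L, 2000L, 3000L),
    segment_mean = c(0.1, -0.3, 0.25)))
  s <- af_sample("S1", c(0.2, 0.3, 0.4, 0.5),
                 loci = data.frame(chrom = "chr1",
                                   pos = c(500L, 1500L, 2500L, 9000L)))
  out <- filter_snvs_by_cnv(s, prof, threshold = 0.2)
  # |0.1| ok, |-0.3| dropped, |0.25| dropped, uncovered kept
  expect_equal(out$afs, c(0.2, 0.5))
  expect_equal(attr(out, "n_uncovered"), 1L)

  neutral <- cnv_profile("S1", data.frame(chrom = "chr1", start = 1L,
                                          end = 10000L, segment_mean = 0))
  expect_equal(filter_snvs_by_cnv(s, neutral)$afs, s$afs)
  expect_equal(filter_snvs_by_cnv(s, prof, threshold = Inf)$afs, s$afs)
})

test_that("auxiliary statistics match direct formula recomputation", {
  sym <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(extra_statistics(sym)[["skewness"]], 0)

  # uniform occupancy histogram attains maximal entropy log(n_bins)
  centers <- seq(0.0125, by = 0.025, length.out = 40)
  expect_equal(extra_statistics(centers)[["entropy"]], log(40))

  set.seed(31)
  x <- runif(60, 0.05, 0.9)
  st <- extra_statistics(x)
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  expect_equal(st[["mean"]], mean(x))
  expect_equal(st[["std"]], sqrt(m2))
  expect_equal(st[["skewness"]], mean((x - mean(x))^3) / m2^1.5)
  expect_equal(st[["excess_kurtosis"]], mean((x - mean(x))^4) / m2^2 - 3)
  expect_equal(st[["iqr"]], unname(diff(quantile(x, c(0.25, 0.75)))))
  expect_equal(st[["frac_gt_0.4"]], mean(x > 0.4))
  expect_equal(st[["n_snvs"]], n)

  # moment-based entries are missing below 3 values
  st2 <- extra_statistics(c(0.2, 0.4))
  expect_true(is.na(st2[["skewness"]]))
  expect_equal(st2[["n_snvs"]], 2)
})

test_that("AF dispersion tracks CNV dispersion in coupled cohorts", {
  # samples whose AF spread is driven by per-locus copy number
  set.seed(37)
  n_samp <- 40
  cnv_stds <- af_stds <- numeric(n_samp)
  for (i in seq_len(n_samp)) {
    sigma <- runif(1, 0.05, 0.6)
    prof <- generate_cnv_profile(30, sigma, seed = i, length_range = c(1e3, 1e4))
    glen <- sum(prof$segments$length)
    pos <- sample.int(glen, 120)
    f <- sample_afs(evo_model_params(0.8), n = 120, seed = i + 1000)
    cl <- cnv_at_locus(prof, rep("chr1", 120), pos)
    cl[is.na(cl)] <- 0
    af <- pmin(pmax(f / 2^cl, 0.02), 0.98)
    af_stds[i] <- af_std(af)
    cnv_stds[i] <- cnv_std_at_snvs(prof, data.frame(chrom = "chr1", pos = pos))
  }
  expect_gt(cor(cnv_stds, af_stds), 0)
})
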