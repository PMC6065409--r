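#' Comparison configuration
#'
#' Bundle of the fixed constants used when comparing allele-frequency
#' distributions between call sets: histogram bin width 0.025, Gaussian KDE
#' kernel sd 0.02 for the cumulative-absolute-difference distance, KDE
#' bandwidth 0.05 for the L2 permutation statistic, 100 label permutations,
#' and significance level 0.05.
#'
#' @param bin_width histogram bin width (fraction of the AF axis).
#' @param kde_sigma Gaussian kernel sd for [kde_abs_diff()].
#' @param l2_bandwidth Gaussian kernel sd for [l2_permutation_test()].
#' @param n_permutations label permutations for the L2 test.
#' @param alpha significance level.
#' @param seed integer seed for the permutation test.
#' @param grid_n number of KDE evaluation points on `[0, 1]`.
#' @return A list with class `comparison_config`.
#' @export
comparison_config <- function(bin_width = 0.025, kde_sigma = 0.02,
                              l2_bandwidth = 0.05, n_permutations = 100,
                              alpha = 0.05, seed = 1L, grid_n = 1001L) {
  stopifnot(bin_width > 0, kde_sigma > 0, l2_bandwidth > 0,
            n_permutations >= 1, alpha > 0, grid_n >= 2)
  structure(list(bin_width = bin_width, kde_sigma = kde_sigma,
                 l2_bandwidth = l2_bandwidth,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = seed, grid_n = as.integer(grid_n)),
            class = "comparison_config")
}

#' Normalized allele-frequency histogram
#'
#' Bins AFs on `[0, 1]` into `ceiling(1/bin_width)` half-open bins
#' `[a, b)`, the last bin closed at 1, and normalizes counts to abundances
#' summing to one.
#'
#' @param afs non-empty numeric vector of AFs in `[0, 1]`.
#' @param bin_width bin width (default 0.025, i.e. 40 bins).
#' @return An object of class `af_histogram` with fields `bin_width`,
#'   `breaks` and `abundances`.
#' @export
histogram_af <- function(afs, bin_width = 0.025) {
  if (!length(afs)) stop("cannot histogram an empty AF vector")
  if (any(afs < 0 | afs > 1)) stop("AFs must lie in [0, 1]")
  n_bins <- as.integer(ceiling(1 / bin_width))
  # tiny epsilon keeps boundary values (e.g. 0.3 / 0.025) in their
  # half-open bin despite floating-point division; 1.0 joins the last bin
  idx <- pmin(floor((afs + 1e-12) / bin_width) + 1L, n_bins)
  structure(list(bin_width = bin_width,
                 breaks = seq(0, by = bin_width, length.out = n_bins + 1L),
                 abundances = tabulate(idx, n_bins) / length(afs)),
            class = "af_histogram")
}

#' Earth mover's distance between two AF histograms
#'
#' One-dimensional optimal-transport cost in units of bins, computed in the
#' chain form: the sum over interior bin boundaries of the absolute
#' cumulative abundance difference,
#' `sum_{i=1}^{N-1} | sum_{j<=i} (f1_j - f2_j) |`.
#' Symmetric, non-negative, zero iff the histograms are equal, and equal to
#' the minimal mass-times-bins transport cost.
#'
#' @param h1,h2 [histogram_af()] objects with identical binning.
#' @return Non-negative distance in bin units.
#' @export
emd <- function(h1, h2) {
  if (!isTRUE(all.equal(h1$bin_width, h2$bin_width)) ||
      length(h1$abundances) != length(h2$abundances))
    stop("histograms must share bin width and bin count")
  cum <- cumsum(h1$abundances - h2$abundances)
  n <- length(cum)
  sum(abs(cum[-n]))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param afs1,afs2 AF vectors, each with at least 2 values.
#' @param exact use the exact small-sample null distribution (default:
#'   asymptotic, the convention for cohort-scale comparisons).
#' @return list with `D` (max ECDF gap) and `p`.
#' @export
ks_compare <- function(afs1, afs2, exact = FALSE) {
  if (length(afs1) < 2 || length(afs2) < 2)
    stop("KS comparison needs at least 2 values on each side")
  kt <- suppressWarnings(stats::ks.test(afs1, afs2, exact = exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

# Gaussian KDE evaluated on a uniform grid over [0, 1]; no boundary
# correction. Chunked so large AF vectors stay memory-bounded.
kde_on_grid <- function(afs, sigma, grid) {
  dens <- numeric(length(grid))
  for (start in seq(1, length(afs), by = 2000L)) {
    block <- afs[start:min(start + 1999L, length(afs))]
    dens <- dens + rowSums(outer(grid, block, stats::dnorm, sd = sigma))
  }
  dens / length(afs)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Cumulative absolute difference of smoothed AF densities
#'
#' Smooths each AF set with a Gaussian kernel (sd `sigma`) into a continuous
#' density, then integrates the absolute difference over `[0, 1]` by the
#' trapezoid rule on a uniform grid. Two identical sets give 0; fully
#' separated interior clusters approach 2.
#'
#' @param afs1,afs2 non-empty AF vectors.
#' @param sigma kernel standard deviation (default 0.02).
#' @param grid_n grid resolution (default 1001 points).
#' @return Non-negative scalar.
#' @export
kde_abs_diff <- function(afs1, afs2, sigma = 0.02, grid_n = 1001L) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!length(afs1) || !length(afs2)) stop("empty AF vector")
  grid <- seq(0, 1, length.out = grid_n)
  trapz(grid, abs(kde_on_grid(afs1, sigma, grid) -
                    kde_on_grid(afs2, sigma, grid)))
}

#' L2 permutation test between AF distributions
#'
#' Statistic: the integrated squared difference of the two Gaussian KDE
#' densities (kernel sd = `bandwidth`). Null distribution by random
#' reassignment of the pooled values to the two labels; the p-value is the
#' fraction of permuted statistics at least as extreme as the observed one
#' (ties count as extreme, so p is never 0). Deterministic given `seed`.
#'
#' @param afs1,afs2 non-empty AF vectors.
#' @param bandwidth kernel sd (default 0.05).
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param add_one apply the add-one correction `(b+1)/(n+1)` instead of the
#'   literal ratio (off by default).
#' @param grid_n grid resolution.
#' @return list with `statistic` and `p`.
#' @export
l2_permutation_test <- function(afs1, afs2, bandwidth = 0.05, n_perm = 100,
                                seed = 1L, add_one = FALSE, grid_n = 1001L) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!length(afs1) || !length(afs2)) stop("empty AF vector")
  grid <- seq(0, 1, length.out = grid_n)
  pooled <- c(afs1, afs2)
  n1 <- length(afs1)
  n <- length(pooled)
  # kernel matrix grid x pooled values: the KDE of any label subset is a
  # column average, so each permutation costs one indicator product
  K <- outer(grid, pooled, stats::dnorm, sd = bandwidth)
  l2_from_membership <- function(in1) {
    d <- rowSums(K[, in1, drop = FALSE]) / sum(in1) -
      rowSums(K[, !in1, drop = FALSE]) / sum(!in1)
    trapz(grid, d^2)
  }
  obs <- l2_from_membership(seq_len(n) <= n1)
  perm <- with_seed(seed, {
    # one signed-membership weight matrix turns all permutations into a
    # single kernel-matrix product
    W <- vapply(seq_len(n_perm), function(i) {
      w <- rep(-1 / (n - n1), n)
      w[sample.int(n, n1)] <- 1 / n1
      w
    }, numeric(n))
    D <- K %*% W
    h <- 1 / (grid_n - 1)
    colSums(D^2 * h) - (D[1, ]^2 + D[grid_n, ]^2) * h / 2
  })
  b <- sum(perm >= obs)
  p <- if (add_one) (b + 1) / (n_perm + 1) else b / n_perm
  list(statistic = obs, p = p)
}

#' Pearson correlation of allele frequencies at shared loci
#'
#' Intersects two call sets on (chrom, pos, alt) keys and correlates their
#' tumor AFs. Needs at least 3 shared loci, else returns `NA`.
#'
#' @param calls1,calls2 [variant_calls()] tables for the same sample from
#'   two callers.
#' @return Pearson r, or `NA_real_` with fewer than 3 shared loci.
#' @export
shared_af_correlation <- function(calls1, calls2) {
  k1 <- paste(calls1$chrom, calls1$pos, calls1$alt, sep = ":")
  k2 <- paste(calls2$chrom, calls2$pos, calls2$alt, sep = ":")
  shared <- intersect(k1, k2)
  if (length(shared) < 3) return(NA_real_)
  a1 <- calls1$tumor_af[match(shared, k1)]
  a2 <- calls2$tumor_af[match(shared, k2)]
  if (stats::sd(a1) == 0 || stats::sd(a2) == 0) return(NA_real_)
  stats::cor(a1, a2)
}

#' All pairwise distances for one sample
#'
#' Convenience wrapper computing the KS, EMD, KDE absolute-difference and
#' L2 permutation comparisons between one sample's AF sets under two
#' callers.
#'
#' @param afs1,afs2 AF vectors.
#' @param config a [comparison_config()].
#' @return One-row `data.frame` with columns `ks_D`, `ks_p`, `emd`,
#'   `kde_abs_diff`, `l2_stat`, `l2_p`.
#' @export
pairwise_af_distances <- function(afs1, afs2, config = comparison_config()) {
  ks <- ks_compare(afs1, afs2)
  e <- emd(histogram_af(afs1, config$bin_width),
           histogram_af(afs2, config$bin_width))
  kd <- kde_abs_diff(afs1, afs2, config$kde_sigma, config$grid_n)
  l2 <- l2_permutation_test(afs1, afs2, config$l2_bandwidth,
                            config$n_permutations, config$seed,
                            grid_n = config$grid_n)
  data.frame(ks_D = ks$D, ks_p = ks$p, emd = e, kde_abs_diff = kd,
             l2_stat = l2$statistic, l2_p = l2$p)
}

#' Cohort-level pairwise caller comparison
#'
#' For every pair of callers, runs the per-sample comparisons over the
#' samples present under both callers and summarizes: the fraction of
#' samples whose KS p-value falls below the Bonferroni-corrected threshold
#' (`alpha` divided by the number of per-sample tests in that pair), and the
#' cohort medians of EMD and of the KDE absolute difference.
#'
#' @param af_by_caller named list: caller -> named list (sample_id -> AF
#'   vector).
#' @param config a [comparison_config()].
#' @return `data.frame` with one row per caller pair: `caller_a`,
#'   `caller_b`, `n_samples`, `bonferroni_threshold`,
#'   `fraction_significant`, `median_emd`, `median_kde_abs_diff`.
#' @export
cohort_pairwise_summary <- function(af_by_caller,
                                    config = comparison_config()) {
  callers <- names(af_by_caller)
  stopifnot(length(callers) >= 2)
  pairs <- utils::combn(callers, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- af_by_caller[[pr[1]]]; b <- af_by_caller[[pr[2]]]
    shared <- intersect(names(a), names(b))
    if (!length(shared)) stop("no shared samples for pair ",
                              pr[1], "-", pr[2])
    res <- do.call(rbind, lapply(shared, function(id)
      pairwise_af_distances(a[[id]], b[[id]], config)))
    thr <- config$alpha / length(shared)
    data.frame(caller_a = pr[1], caller_b = pr[2],
               n_samples = length(shared), bonferroni_threshold = thr,
               fraction_significant = mean(res$ks_p < thr),
               median_emd = stats::median(res$emd),
               median_kde_abs_diff = stats::median(res$kde_abs_diff),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
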