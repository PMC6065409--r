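#' MATH score of an allele-frequency set
#'
#' Mutant-Allele Tumor Heterogeneity: 100 times the scaled median absolute
#' deviation of the tumor AFs divided by their median,
#' `MATH = 100 * (1.4826 * median(|x - median(x)|)) / median(x)`.
#' The scaling uses the normal-consistency constant 1.4826, so the prefactor
#' of the model's closed form is 148.26. MATH is invariant to multiplying
#' all AFs by a constant, hence nominally insensitive to tumor purity. Any
#' non-negative score vector can be supplied, so cancer-cell-fraction values
#' from external tools are scored identically.
#'
#' @param afs non-empty numeric vector (AFs or CCFs).
#' @param mad_constant scaled-MAD consistency constant (default 1.4826).
#' @return MATH score in percent.
#' @export
math_score <- function(afs, mad_constant = 1.4826) {
  if (!length(afs)) stop("cannot score an empty AF vector")
  med <- stats::median(afs)
  if (med == 0) stop("median AF is zero; MATH undefined")
  100 * stats::mad(afs, constant = mad_constant) / med
}

#' Population standard deviation of allele frequencies
#'
#' Computed with denominator n (ddof 0), for consistency with the
#' length-weighted copy-number dispersion.
#'
#' @param afs numeric vector.
#' @return Standard deviation, or `NA_real_` for fewer than 2 values.
#' @export
af_std <- function(afs) {
  n <- length(afs)
  if (n < 2) return(NA_real_)
  sqrt(mean((afs - mean(afs))^2))
}

#' Copy-number dispersion at mutated loci
#'
#' Looks up the segment mean at every SNV locus and returns the population
#' standard deviation of those values. Loci not covered by any segment are
#' dropped.
#'
#' @param profile a [cnv_profile()].
#' @param loci `data.frame` with columns `chrom`, `pos`.
#' @return Standard deviation, or `NA_real_` with fewer than 2 covered loci.
#' @export
cnv_std_at_snvs <- function(profile, loci) {
  vals <- cnv_at_locus(profile, loci$chrom, loci$pos)
  vals <- vals[!is.na(vals)]
  af_std(vals)
}

#' Whole-genome copy-number standard deviation
#'
#' Length-weighted population standard deviation of segment means,
#' `sqrt(sum_i p_i (c_i - cbar)^2)` with `p_i = l_i / sum_j l_j` and
#' `cbar = sum_i p_i c_i` - equivalent to sampling the genome uniformly
#' per-base and taking the standard deviation of the segment mean at each
#' position. Independent of where the SNVs fall.
#'
#' @param profile a [cnv_profile()] with at least one segment.
#' @return Weighted standard deviation (a single segment gives 0).
#' @export
wg_cnv_std <- function(profile) {
  s <- profile$segments
  if (!nrow(s)) stop("profile has no segments")
  l <- as.double(s$length)
  tot <- sum(l)
  if (tot <= 0) stop("zero total segment length")
  p <- l / tot
  cbar <- sum(p * s$segment_mean)
  sqrt(sum(p * (s$segment_mean - cbar)^2))
}

#' Remove SNVs at copy-number-aberrant loci
#'
#' Drops SNVs whose covering segment has `|segment mean| > threshold`,
#' retaining copy-neutral loci. Loci uncovered by any segment are retained
#' under a copy-neutral assumption; their count is recorded in the
#' `n_uncovered` attribute of the result.
#'
#' @param sample an [af_sample()] carrying loci.
#' @param profile the sample's [cnv_profile()].
#' @param threshold absolute segment-mean cutoff (default 0.2).
#' @return The filtered [af_sample()].
#' @export
filter_snvs_by_cnv <- function(sample, profile, threshold = 0.2) {
  if (is.null(sample$loci)) stop("sample carries no loci")
  vals <- cnv_at_locus(profile, sample$loci$chrom, sample$loci$pos)
  keep <- is.na(vals) | abs(vals) <= threshold
  out <- af_sample(sample$sample_id, sample$afs[keep],
                   sample$loci[keep, , drop = FALSE],
                   cohort = sample$cohort, caller = sample$caller,
                   purity = sample$purity)
  attr(out, "n_uncovered") <- sum(is.na(vals))
  out
}

# Central sample moments with denominator n.
moment_n <- function(x, k) mean((x - mean(x))^k)

#' Auxiliary summary statistics of an AF distribution
#'
#' A configurable battery of distribution descriptors beyond MATH: mean,
#' median, population sd, skewness, excess kurtosis, IQR, 0.1/0.9
#' quantiles, Shannon entropy of the 0.025-binned histogram, Sarle's
#' bimodality coefficient, the fraction of AFs above 0.4 (near-clonal
#' mass), and the SNV count. Moment-based entries are `NA` below 3 values.
#'
#' @param afs numeric AF vector.
#' @param bin_width histogram bin width for the entropy term.
#' @return Named numeric vector.
#' @export
extra_statistics <- function(afs, bin_width = 0.025) {
  n <- length(afs)
  out <- c(mean = NA_real_, median = NA_real_, std = NA_real_,
           skewness = NA_real_, excess_kurtosis = NA_real_, iqr = NA_real_,
           q10 = NA_real_, q90 = NA_real_, entropy = NA_real_,
           bimodality = NA_real_, frac_gt_0.4 = NA_real_, n_snvs = n)
  if (n < 3) return(out)
  m2 <- moment_n(afs, 2)
  g1 <- if (m2 > 0) moment_n(afs, 3) / m2^1.5 else 0
  g2 <- if (m2 > 0) moment_n(afs, 4) / m2^2 - 3 else 0
  h <- histogram_af(afs, bin_width)$abundances
  h <- h[h > 0]
  bimod <- if (n > 3) {
    (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  } else NA_real_
  out["mean"] <- mean(afs)
  out["median"] <- stats::median(afs)
  out["std"] <- sqrt(m2)
  out["skewness"] <- g1
  out["excess_kurtosis"] <- g2
  out["iqr"] <- unname(diff(stats::quantile(afs, c(0.25, 0.75))))
  out["q10"] <- unname(stats::quantile(afs, 0.1))
  out["q90"] <- unname(stats::quantile(afs, 0.9))
  out["entropy"] <- -sum(h * log(h))
  out["bimodality"] <- bimod
  out["frac_gt_0.4"] <- mean(afs > 0.4)
  out
}

#' Per-sample heterogeneity score panel
#'
#' Computes the full score set for one AF sample: MATH, AF standard
#' deviation, copy-number dispersion at the mutated loci, whole-genome
#' copy-number dispersion, SNV count, and the auxiliary statistics.
#'
#' @param sample an [af_sample()].
#' @param profile optional [cnv_profile()] for the same sample.
#' @return One-row `data.frame`.
#' @export
heterogeneity_scores <- function(sample, profile = NULL) {
  data.frame(
    sample_id = sample$sample_id,
    caller = sample$caller,
    math = math_score(sample$afs),
    af_std = af_std(sample$afs),
    cnv_std = if (!is.null(profile) && !is.null(sample$loci))
      cnv_std_at_snvs(profile, sample$loci) else NA_real_,
    wg_cnv_std = if (!is.null(profile)) wg_cnv_std(profile) else NA_real_,
    n_snvs = length(sample$afs),
    stringsAsFactors = FALSE
  )
}
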