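#' Expression dataset container
#'
#' Patients-by-genes matrices of RPKM expression, gene-level CNV
#' (log2 copy ratio) and binary SNV status (1 if the gene carries a somatic
#' SNV in that patient), with the two CNV thresholds: `c1_th` below which a
#' gene counts as not amplified, and `c2_th` above which it counts as
#' amplified.
#'
#' @param rpkm non-negative patients x genes matrix.
#' @param cnv log2-ratio matrix of the same shape.
#' @param snv binary matrix of the same shape.
#' @param c1_th no-amplification threshold (default 0.1).
#' @param c2_th amplification threshold (default 1.0).
#' @return List of class `expression_dataset`.
#' @export
expression_dataset <- function(rpkm, cnv, snv, c1_th = 0.1, c2_th = 1.0) {
  rpkm <- as.matrix(rpkm); cnv <- as.matrix(cnv); snv <- as.matrix(snv)
  stopifnot(identical(dim(rpkm), dim(cnv)), identical(dim(rpkm), dim(snv)),
            all(rpkm >= 0), all(snv %in% c(0, 1)), c2_th > c1_th)
  if (is.null(colnames(rpkm))) colnames(rpkm) <- paste0("g", seq_len(ncol(rpkm)))
  colnames(cnv) <- colnames(snv) <- colnames(rpkm)
  structure(list(rpkm = rpkm, cnv = cnv, snv = snv,
                 c1_th = c1_th, c2_th = c2_th),
            class = "expression_dataset")
}

#' Unit step function (strictly positive arguments)
#'
#' `u(x) = 0` for `x <= 0` and `1` for `x > 0`; zero maps to zero.
#'
#' @param x numeric (vectorized).
#' @return 0/1 numeric of the same shape.
#' @export
step_u <- function(x) (x > 0) + 0

#' Positive-element column average
#'
#' For each gene (column), the sum of the column divided by the number of
#' strictly positive entries - the mean over qualifying patients when the
#' matrix is a masked product of non-negative values. A gene with no
#' positive entry is discarded (returned as `NA`).
#'
#' @param x patients x genes matrix.
#' @return Named per-gene numeric vector.
#' @export
positive_mean_by_gene <- function(x) {
  x <- as.matrix(x)
  denom <- colSums(step_u(x))
  out <- colSums(x) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Mean expression by amplification/SNV category
#'
#' Applies the positive-element average to three masked products of the
#' RPKM matrix: amplified genes carrying an SNV
#' (`r * u(c - c2_th) * s`), non-amplified genes without an SNV
#' (`r * u(c1_th - c) * (1 - s)`), and amplified genes without an SNV
#' (`r * u(c - c2_th) * (1 - s)`). For `c2_th > c1_th` the amplified and
#' non-amplified masks are mutually exclusive per cell. Genes with no
#' qualifying patient in a category are discarded (`NA`) in that category.
#'
#' @param ds an [expression_dataset()].
#' @return `data.frame` with per-gene columns `amp_with_snv`,
#'   `noamp_no_snv`, `amp_no_snv`.
#' @export
category_means <- function(ds) {
  amp <- step_u(ds$cnv - ds$c2_th)
  noamp <- step_u(ds$c1_th - ds$cnv)
  data.frame(
    gene = colnames(ds$rpkm),
    amp_with_snv = positive_mean_by_gene(ds$rpkm * amp * ds$snv),
    noamp_no_snv = positive_mean_by_gene(ds$rpkm * noamp * (1 - ds$snv)),
    amp_no_snv = positive_mean_by_gene(ds$rpkm * amp * (1 - ds$snv)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Paired comparison of two per-gene category means
#'
#' Over genes present in both categories, reports the fraction of genes
#' where the first mean exceeds the second (exact ties excluded from the
#' denominator) and a Wilcoxon signed-rank p-value. The exact null is used
#' below 25 pairs, the tie-corrected normal approximation otherwise.
#'
#' @param means_a,means_b per-gene numeric vectors (same genes).
#' @param min_genes minimum paired genes required (default 10).
#' @return list with `fraction_greater`, `p`, `n_genes`.
#' @export
compare_categories <- function(means_a, means_b, min_genes = 10) {
  ok <- !is.na(means_a) & !is.na(means_b)
  a <- means_a[ok]; b <- means_b[ok]
  if (length(a) < min_genes)
    stop("too few genes present in both categories (", length(a), ")")
  nz <- a != b
  frac <- if (any(nz)) mean(a[nz] > b[nz]) else NA_real_
  p <- if (!any(nz)) 1 else {
    suppressWarnings(stats::wilcox.test(
      a, b, paired = TRUE, exact = sum(nz) < 25))$p.value
  }
  list(fraction_greater = frac, p = p, n_genes = length(a))
}

#' Drop listed gene symbols from an expression dataset
#'
#' Removes the matrix columns whose symbols appear in any of the supplied
#' lists (e.g. tumor-suppressor and oncogene catalogs). Symbols not present
#' in the dataset are ignored; their count is recorded in the
#' `n_unmatched` attribute.
#'
#' @param ds an [expression_dataset()].
#' @param symbols_to_drop character vector of gene symbols.
#' @return The reduced [expression_dataset()].
#' @export
exclude_gene_lists <- function(ds, symbols_to_drop) {
  symbols_to_drop <- unique(symbols_to_drop)
  hit <- colnames(ds$rpkm) %in% symbols_to_drop
  out <- expression_dataset(ds$rpkm[, !hit, drop = FALSE],
                            ds$cnv[, !hit, drop = FALSE],
                            ds$snv[, !hit, drop = FALSE],
                            ds$c1_th, ds$c2_th)
  attr(out, "n_unmatched") <-
    sum(!symbols_to_drop %in% colnames(ds$rpkm))
  out
}

#' Read one-symbol-per-line gene lists
#'
#' @param paths one or more plain-text files, one gene symbol per line.
#' @return Character vector of unique symbols.
#' @export
read_gene_list <- function(paths) {
  unique(unlist(lapply(paths, function(p) {
    x <- readLines(p, warn = FALSE)
    x <- trimws(x)
    x[nzchar(x)]
  })))
}
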