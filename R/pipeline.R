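#' Study run configuration
#'
#' Paths and fixed constants for the end-to-end study. The thresholds
#' collect the analysis constants in one place: 0.025 AF histogram bins,
#' KDE sigma 0.02, L2 bandwidth 0.05, 100 permutations, copy-number cutoff
#' 0.2, depth filter 50, AF filter 0.1, purity filter 0.8, 1460-day
#' horizon, alpha 0.05.
#'
#' @param input_dir directory holding the cohort files (layout of
#'   [generate_cohort()]).
#' @param out_dir output directory.
#' @param callers caller dialects expected per sample.
#' @param cohort cohort tag.
#' @param min_depth,min_af,cnv_threshold,min_purity,horizon_days,alpha
#'   analysis constants.
#' @param comparison a [comparison_config()].
#' @param seed integer seed fanned out to the stochastic stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir,
                       callers = c("mutect", "somaticsniper", "varscan"),
                       cohort = "SYNTH",
                       min_depth = 50, min_af = 0.1, cnv_threshold = 0.2,
                       min_purity = 0.8, horizon_days = 1460, alpha = 0.05,
                       comparison = comparison_config(), seed = 1L) {
  stopifnot(dir.exists(input_dir), min_depth > 0, min_af > 0,
            cnv_threshold > 0, horizon_days > 0, alpha > 0)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 callers = callers, cohort = cohort, min_depth = min_depth,
                 min_af = min_af, cnv_threshold = cnv_threshold,
                 min_purity = min_purity, horizon_days = horizon_days,
                 alpha = alpha, comparison = comparison,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the full heterogeneity-robustness study
#'
#' Executes the pipeline stages in order on a cohort directory: (1) parse
#' and filter the per-caller VCFs into AF samples; (2) pairwise caller
#' comparison of AF distributions (per-sample distances and the cohort
#' summary with the Bonferroni-corrected significant fraction); (3)
#' per-sample heterogeneity and copy-number scores; (4) median-split
#' log-rank survival analysis for each caller and score type, with BH
#' correction across the grid; (5) expression category comparison; (6)
#' score correlation table (CNV dispersion vs MATH and AF std). Each stage
#' writes a TSV under `out_dir`; a JSON manifest records the seed and
#' configuration. Reruns with the same config and inputs are
#' deterministic. A stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_study <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  truth <- read_truth_table(config$input_dir)
  ids <- truth$sample_id
  profiles <- run_stage("load", read_seg(file.path(config$input_dir,
                                                   "cohort.seg")))
  clinical <- run_stage("load", read_clinical(file.path(config$input_dir,
                                                        "clinical.tsv")))

  samples <- run_stage("filter", {
    out <- list()
    for (caller in config$callers) {
      out[[caller]] <- list()
      for (id in ids) {
        calls <- read_vcf_calls(
          file.path(config$input_dir, paste0(id, ".", caller, ".vcf")),
          caller)
        n_raw <- nrow(calls)
        calls <- apply_postprocessing_filters(calls, config$min_depth,
                                              config$min_af)
        out[[caller]][[id]] <- calls_to_af_sample(
          calls, id, cohort = config$cohort,
          purity = truth$purity[match(id, truth$sample_id)])
        if (id == ids[1])
          stage_log("filter", "%s %s: %d -> %d calls", id, caller, n_raw,
                    nrow(calls))
      }
    }
    out
  })

  compare <- run_stage("compare", {
    afs <- lapply(samples, function(by_id) lapply(by_id, `[[`, "afs"))
    cmp_cfg <- config$comparison
    cmp_cfg$seed <- child_seed(config$seed, 10L)
    summary <- cohort_pairwise_summary(afs, cmp_cfg)
    per_sample <- do.call(rbind, lapply(
      utils::combn(config$callers, 2, simplify = FALSE), function(pr) {
        rows <- do.call(rbind, lapply(ids, function(id) {
          r <- pairwise_af_distances(afs[[pr[1]]][[id]], afs[[pr[2]]][[id]],
                                     cmp_cfg)
          r$shared_af_correlation <- shared_af_correlation(
            calls_from_sample(samples[[pr[1]]][[id]]),
            calls_from_sample(samples[[pr[2]]][[id]]))
          cbind(data.frame(sample_id = id, caller_pair = paste(pr, collapse = "-"),
                           stringsAsFactors = FALSE), r)
        }))
        rows
      }))
    write_tsv(per_sample, file.path(config$out_dir, "compare.tsv"))
    write_tsv(summary, file.path(config$out_dir, "compare_summary.tsv"))
    list(per_sample = per_sample, summary = summary)
  })

  scores <- run_stage("score", {
    rows <- do.call(rbind, lapply(config$callers, function(caller) {
      do.call(rbind, lapply(ids, function(id) {
        heterogeneity_scores(samples[[caller]][[id]], profiles[[id]])
      }))
    }))
    rows$cohort <- config$cohort
    rows <- rows[order(rows$caller, rows$sample_id), , drop = FALSE]
    write_tsv(rows, file.path(config$out_dir, "scores.tsv"))
    rows
  })

  surv <- run_stage("survive", {
    grid <- do.call(rbind, lapply(
      c("math", "cnv_std", "wg_cnv_std"), function(score_name) {
        do.call(rbind, lapply(config$callers, function(caller) {
          sc <- scores[scores$caller == caller, , drop = FALSE]
          v <- stats::setNames(sc[[score_name]], sc$sample_id)
          v <- v[!is.na(v)]
          logrank_median_split(v, clinical, config$horizon_days,
                               cohort = config$cohort, caller = caller,
                               score_name = score_name)
        }))
      }))
    grid$significant_raw <- grid$logrank_p < config$alpha
    grid$significant_bh <- NA
    for (sn in unique(grid$score_name)) {
      sel <- grid$score_name == sn
      grid$significant_bh[sel] <- bh_correct(grid$logrank_p[sel],
                                             config$alpha)
    }
    grid <- grid[order(grid$score_name, grid$caller), , drop = FALSE]
    write_tsv(grid, file.path(config$out_dir, "survival_grid.tsv"))
    grid
  })

  express <- run_stage("express", {
    ds <- expression_dataset(
      read_matrix_tsv(file.path(config$input_dir, "rpkm.tsv")),
      read_matrix_tsv(file.path(config$input_dir, "cnv_genes.tsv")),
      read_matrix_tsv(file.path(config$input_dir, "snv_genes.tsv")))
    cm <- category_means(ds)
    res <- data.frame(
      comparison = c("amp_with_snv_vs_noamp_no_snv",
                     "amp_with_snv_vs_amp_no_snv"),
      stringsAsFactors = FALSE)
    empty <- list(fraction_greater = NA_real_, p = NA_real_, n_genes = 0L)
    c1 <- tryCatch(compare_categories(cm$amp_with_snv, cm$noamp_no_snv),
                   error = function(e) empty)
    c2 <- tryCatch(compare_categories(cm$amp_with_snv, cm$amp_no_snv),
                   error = function(e) empty)
    res$fraction_greater <- c(c1$fraction_greater, c2$fraction_greater)
    res$p <- c(c1$p, c2$p)
    res$n_genes <- c(c1$n_genes, c2$n_genes)
    write_tsv(res, file.path(config$out_dir, "expression.tsv"))
    list(category_means = cm, comparisons = res)
  })

  correlations <- run_stage("correlate", {
    rows <- do.call(rbind, lapply(config$callers, function(caller) {
      sc <- scores[scores$caller == caller, , drop = FALSE]
      data.frame(cohort = config$cohort, caller = caller,
                 cor_cnvstd_math = stats::cor(sc$cnv_std, sc$math,
                                              use = "complete.obs"),
                 cor_cnvstd_afstd = stats::cor(sc$cnv_std, sc$af_std,
                                               use = "complete.obs"),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(rows, file.path(config$out_dir, "correlations.tsv"))
    rows
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("hetrobust")),
    seed = config$seed,
    cohort = config$cohort,
    n_samples = length(ids),
    callers = config$callers,
    thresholds = config[c("min_depth", "min_af", "cnv_threshold",
                          "min_purity", "horizon_days", "alpha")],
    input_checksums = as.list(tools::md5sum(
      sort(list.files(config$input_dir, full.names = TRUE)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(compare = compare, scores = scores, survival = surv,
                 expression = express, correlations = correlations,
                 manifest = manifest))
}

# Rebuild a minimal calls table from an af_sample (for shared-locus AF
# correlation inside the pipeline; alt alleles are not tracked there, so
# the key degrades to chrom:pos).
calls_from_sample <- function(s) {
  data.frame(chrom = s$loci$chrom, pos = s$loci$pos, alt = "N",
             tumor_af = s$afs, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cohort-by-caller significance grid
#'
#' Reshapes median-split test results into a cohort x caller matrix of
#' log-rank p-values with two-level significance flags: `*` below the raw
#' alpha, `**` surviving BH correction across the whole grid.
#'
#' @param results rows as returned by [logrank_median_split()] (one score
#'   type at a time).
#' @param alpha significance level (default 0.05).
#' @return list with matrices `p`, `flag` (strings "", "*", "**").
#' @export
grid_summary <- function(results, alpha = 0.05) {
  if (!nrow(results))
    return(list(p = matrix(numeric(), 0, 0), flag = matrix(character(), 0, 0)))
  cohorts <- unique(results$cohort)
  callers <- unique(results$caller)
  p <- matrix(NA_real_, length(cohorts), length(callers),
              dimnames = list(cohorts, callers))
  for (i in seq_len(nrow(results)))
    p[results$cohort[i], results$caller[i]] <- results$logrank_p[i]
  v <- as.vector(p)
  fl <- rep(NA, length(v))
  fl[!is.na(v)] <- bh_correct(v[!is.na(v)], alpha)
  bh <- matrix(fl, nrow(p), ncol(p), dimnames = dimnames(p))
  flag <- ifelse(!is.na(p) & bh, "**",
                 ifelse(!is.na(p) & p < alpha, "*", ""))
  list(p = p, flag = flag)
}
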