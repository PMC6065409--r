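#' Synthetic cohort configuration
#'
#' Parameters of the TCGA-like cohort generator. Defaults describe the
#' study conditions the analysis assumes: per-sample AF sets drawn from the
#' linear-evolution model (clonal peak at 0.5 plus a 1/f neutral tail above
#' `f_min = 0.1`) at read depth 100; segmented copy-number profiles whose
#' per-sample dispersion `sigma_c` spans a realistic range; three caller
#' dialects that disagree mostly on which loci are called (Bernoulli
#' retention plus spiked false calls) while agreeing closely on AFs at
#' shared loci (small jitter); and exponential survival whose log-hazard is
#' linear in the standardized copy-number dispersion.
#'
#' @param n_samples cohort size.
#' @param cohort cohort tag written into outputs.
#' @param snvs_per_sample inclusive range of somatic SNV counts per sample.
#' @param w_range neutral-fraction range sampled uniformly per sample.
#' @param f_min minimum measurable AF.
#' @param read_depth mean sequencing depth (tumor and normal).
#' @param n_cnv_segments range of segment counts per sample.
#' @param segment_length range of segment lengths (bp).
#' @param sigma_c_range range of per-sample segment-mean dispersions.
#' @param cnv_coupling couple AFs to local copy number (mutant allele on
#'   one of `2 * 2^c` copies), so AF dispersion tracks CNV dispersion.
#' @param callers named list of per-caller models, each with `sensitivity`
#'   (retention probability), `false_rate` (spiked false calls per true
#'   call), `jitter_sd` (caller-specific AF reporting jitter).
#' @param survival list: `h0` baseline daily hazard, `beta` log-hazard per
#'   sd of copy-number dispersion, `censor_max` upper bound of the uniform
#'   administrative censoring time (days).
#' @param expression list: `n_genes`, `base_rpkm`, `noise_sdlog`,
#'   `snv_rate`.
#' @param purity_range per-sample purity range.
#' @param exact_af record AFs without read-count quantization or jitter
#'   (for noise-free checks).
#' @param seed mandatory integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 50L,
                          cohort = "SYNTH",
                          snvs_per_sample = c(100L, 300L),
                          w_range = c(0.3, 1),
                          f_min = 0.1,
                          read_depth = 100L,
                          n_cnv_segments = c(40L, 60L),
                          segment_length = c(5e5, 5e6),
                          sigma_c_range = c(0.05, 0.6),
                          cnv_coupling = TRUE,
                          callers = list(
                            mutect = list(sensitivity = 0.95,
                                          false_rate = 0.05,
                                          jitter_sd = 0.01),
                            somaticsniper = list(sensitivity = 0.85,
                                                 false_rate = 0.08,
                                                 jitter_sd = 0.01),
                            varscan = list(sensitivity = 0.80,
                                           false_rate = 0.03,
                                           jitter_sd = 0.01)),
                          survival = list(h0 = 1 / 1200, beta = 1.0,
                                          censor_max = 2 * 1460),
                          expression = list(n_genes = 60L, base_rpkm = 10,
                                            noise_sdlog = 0.3,
                                            snv_rate = 0.15,
                                            amp_rate = 0.1,
                                            amp_gain = c(1, 2.5)),
                          purity_range = c(0.6, 1),
                          exact_af = FALSE,
                          seed) {
  if (missing(seed)) stop("cohort_config requires an explicit seed")
  stopifnot(n_samples >= 2, f_min > 0, f_min < 0.5, read_depth >= 1,
            all(vapply(callers, function(k)
      k$sensitivity > 0 && k$sensitivity <= 1 && k$false_rate >= 0 &&
        k$jitter_sd >= 0, logical(1))))
  structure(list(n_samples = as.integer(n_samples), cohort = cohort,
                 snvs_per_sample = as.integer(snvs_per_sample),
                 w_range = w_range, f_min = f_min,
                 read_depth = as.integer(read_depth),
                 n_cnv_segments = as.integer(n_cnv_segments),
                 segment_length = segment_length,
                 sigma_c_range = sigma_c_range,
                 cnv_coupling = cnv_coupling, callers = callers,
                 survival = survival, expression = expression,
                 purity_range = purity_range, exact_af = exact_af,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate one copy-number profile
#'
#' Contiguous non-overlapping segments on one chromosome with
#' Normal(0, `sigma_c`) segment means; with many equal-length segments the
#' whole-genome CNV standard deviation concentrates near `sigma_c`.
#'
#' @param n_segments number of segments (>= 1).
#' @param sigma_c segment-mean dispersion.
#' @param seed integer seed.
#' @param sample_id profile label.
#' @param length_range segment length range (bp).
#' @param chrom chromosome name.
#' @return A [cnv_profile()].
#' @export
generate_cnv_profile <- function(n_segments, sigma_c, seed,
                                 sample_id = "S1",
                                 length_range = c(5e5, 5e6),
                                 chrom = "chr1") {
  stopifnot(n_segments >= 1, sigma_c >= 0)
  with_seed(seed, {
    lens <- round(stats::runif(n_segments, length_range[1], length_range[2]))
    ends <- cumsum(lens)
    starts <- c(1, head(ends, -1) + 1)
    means <- if (sigma_c > 0) stats::rnorm(n_segments, 0, sigma_c)
             else rep(0, n_segments)
    cnv_profile(sample_id,
                data.frame(chrom = chrom, start = starts, end = ends,
                           segment_mean = means, stringsAsFactors = FALSE))
  })
}

# Observed AF at a locus: mutant allele on one of the 2 * 2^c copies of a
# tumor cell carrying it; cell fraction 2f under copy-neutrality. Reduces
# to f at c = 0.
couple_af_to_cnv <- function(f, c_local) {
  pmin(pmax(f / (2^c_local), 0.02), 0.98)
}

vcf_header <- function(caller, sample_id) {
  fmt <- switch(caller,
    mutect = c(
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=FA,Number=A,Type=Float,Description="Allele fraction of the alternate allele">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    varscan = c(
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=FREQ,Number=1,Type=String,Description="Variant allele frequency">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    somaticsniper = c(
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      '##FORMAT=<ID=DP4,Number=4,Type=Integer,Description="Ref-forward, ref-reverse, alt-forward, alt-reverse read counts">'))
  c("##fileformat=VCFv4.2",
    sprintf("##source=synthetic-%s-like", caller),
    sprintf("##SAMPLE=<ID=TUMOR,SampleName=%s>", sample_id),
    "##contig=<ID=chr1>",
    fmt,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR")
}

# Write one caller-dialect VCF for one sample. `rec` carries pos, ref, alt,
# af (tumor), tumor_depth, normal_depth, filter, normal_af.
write_caller_vcf <- function(rec, caller, sample_id, path) {
  fmt_rec <- switch(caller,
    mutect = list(
      key = "GT:FA:DP",
      normal = sprintf("0/0:%s:%d", format_af(rec$normal_af), rec$normal_depth),
      tumor = sprintf("0/1:%s:%d", format_af(rec$af), rec$tumor_depth)),
    varscan = list(
      key = "GT:FREQ:DP",
      normal = sprintf("0/0:%s%%:%d", formatC(100 * rec$normal_af, format = "f", digits = 2), rec$normal_depth),
      tumor = sprintf("0/1:%s%%:%d", formatC(100 * rec$af, format = "f", digits = 2), rec$tumor_depth)),
    somaticsniper = {
      alt_t <- round(rec$af * rec$tumor_depth)
      alt_n <- round(rec$normal_af * rec$normal_depth)
      list(
        key = "GT:DP:DP4",
        normal = sprintf("0/0:%d:%d,%d,%d,%d", rec$normal_depth,
                         ceiling((rec$normal_depth - alt_n) / 2),
                         floor((rec$normal_depth - alt_n) / 2),
                         ceiling(alt_n / 2), floor(alt_n / 2)),
        tumor = sprintf("0/1:%d:%d,%d,%d,%d", rec$tumor_depth,
                        ceiling((rec$tumor_depth - alt_t) / 2),
                        floor((rec$tumor_depth - alt_t) / 2),
                        ceiling(alt_t / 2), floor(alt_t / 2)))
    })
  body <- sprintf("chr1\t%d\t.\t%s\t%s\t.\t%s\t.\t%s\t%s\t%s",
                  rec$pos, rec$ref, rec$alt, rec$filter,
                  fmt_rec$key, fmt_rec$normal, fmt_rec$tumor)
  writeLines(c(vcf_header(caller, sample_id), body), path)
  invisible(path)
}

format_af <- function(x) formatC(x, format = "f", digits = 4)

BASES <- c("A", "C", "G", "T")

# Per-sample caller call sets derived from a master somatic call set:
# Bernoulli retention shaped by an AF-dependent dropout near f_min, small
# caller-specific AF jitter, and spiked false calls; a few records are
# given non-PASS FILTERs or contaminated normals so the postprocessing
# filters have work to do.
derive_caller_calls <- function(master, caller_model, caller, f_min,
                                read_depth, genome_len, exact_af, seed) {
  with_seed(seed, {
    p_keep <- caller_model$sensitivity *
      stats::plogis((master$af_true - f_min) / 0.03)
    keep <- stats::runif(nrow(master)) < p_keep
    calls <- master[keep, , drop = FALSE]
    n <- nrow(calls)
    af <- calls$af_binom
    if (!exact_af && caller_model$jitter_sd > 0)
      af <- pmin(pmax(af + stats::rnorm(n, 0, caller_model$jitter_sd),
                      0.001), 0.999)
    if (exact_af) af <- calls$af_true
    calls$af <- af
    calls$filter <- "PASS"
    calls$normal_af <- 0

    # a sprinkle of records the postprocessing filters must remove
    if (n > 0 && !exact_af) {
      rej <- stats::runif(n) < 0.02
      if (caller %in% c("mutect", "varscan"))
        calls$filter[rej] <- "REJECT"
      contam <- stats::runif(n) < 0.02
      calls$normal_af[contam] <- stats::runif(sum(contam), 0.02, 0.08)
    }

    n_false <- stats::rbinom(1, nrow(master), caller_model$false_rate)
    if (n_false > 0) {
      fp_pos <- sample.int(genome_len, n_false)
      fp <- data.frame(
        pos = fp_pos,
        ref = sample(BASES, n_false, replace = TRUE),
        alt = NA_character_,
        af_true = stats::runif(n_false, f_min, 0.3),
        stringsAsFactors = FALSE)
      fp$alt <- vapply(fp$ref, function(r)
        sample(setdiff(BASES, r), 1), character(1))
      fp$af <- fp$af_true
      fp$af_binom <- fp$af_true
      fp$tumor_depth <- stats::rpois(n_false, read_depth * 1.5)
      fp$normal_depth <- stats::rpois(n_false, read_depth * 1.5)
      fp$filter <- "PASS"
      fp$normal_af <- 0
      calls <- rbind(calls[names(fp)], fp)
    }
    calls <- calls[order(calls$pos), , drop = FALSE]
    calls[!duplicated(calls$pos), , drop = FALSE]
  })
}

#' Generate a synthetic TCGA-like cohort on disk
#'
#' Writes, under `out_dir`: one VCF per sample and caller dialect
#' (`<sample>.<caller>.vcf`), a cohort SEG file (`cohort.seg`), a clinical
#' TSV (`clinical.tsv`), gene-level expression matrices (`rpkm.tsv`,
#' `cnv_genes.tsv`, `snv_genes.tsv`), and a `truth.tsv` recording every
#' latent per-sample parameter. Regeneration under the same config and
#' seed is byte-identical.
#'
#' Per sample: a neutral fraction `w` and copy-number dispersion `sigma_c`
#' are drawn; true AFs come from the evolution model, optionally coupled to
#' the local segment mean; read counts at the configured depth quantize
#' the recorded AFs; each caller retains loci with its sensitivity (with
#' extra dropout near `f_min`), jitters AFs slightly, and spikes false
#' calls, so call sets disagree while shared-locus AFs stay tightly
#' correlated. Survival times are exponential with hazard
#' `h0 * exp(beta * z)` where `z` is the cohort-standardized true
#' whole-genome CNV std; censoring is uniform administrative.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the truth table `data.frame`.
#' @export
generate_cohort <- function(config, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)

  n <- config$n_samples
  ids <- sprintf("%s-%03d", config$cohort, seq_len(n))

  latent <- with_seed(child_seed(config$seed, 1L), {
    data.frame(
      sample_id = ids,
      w = stats::runif(n, config$w_range[1], config$w_range[2]),
      sigma_c = stats::runif(n, config$sigma_c_range[1],
                             config$sigma_c_range[2]),
      n_snvs = sample(seq(config$snvs_per_sample[1],
                          config$snvs_per_sample[2]), n, replace = TRUE),
      n_segments = sample(seq(config$n_cnv_segments[1],
                              config$n_cnv_segments[2]), n, replace = TRUE),
      purity = stats::runif(n, config$purity_range[1],
                            config$purity_range[2]),
      stringsAsFactors = FALSE)
  })

  profiles <- vector("list", n)
  names(profiles) <- ids
  truth <- latent
  truth$wg_cnv_std <- NA_real_

  for (i in seq_len(n)) {
    profiles[[i]] <- generate_cnv_profile(
      latent$n_segments[i], latent$sigma_c[i],
      seed = child_seed(config$seed, 100L + i), sample_id = ids[i],
      length_range = config$segment_length)
    truth$wg_cnv_std[i] <- wg_cnv_std(profiles[[i]])
    genome_len <- sum(as.double(profiles[[i]]$segments$length))

    master <- with_seed(child_seed(config$seed, 200L + i), {
      m <- latent$n_snvs[i]
      pos <- sort(sample.int(genome_len, m))
      f <- sample_afs(evo_model_params(latent$w[i], config$f_min),
                      n = m, seed = NULL)
      if (config$cnv_coupling) {
        c_loc <- cnv_at_locus(profiles[[i]], rep("chr1", m), pos)
        c_loc[is.na(c_loc)] <- 0
        f <- couple_af_to_cnv(f, c_loc)
      }
      ref <- sample(BASES, m, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1),
                    character(1))
      td <- stats::rpois(m, config$read_depth * 1.5)
      nd <- stats::rpois(m, config$read_depth * 1.5)
      af_binom <- if (config$exact_af) f else
        stats::rbinom(m, pmax(td, 1), f) / pmax(td, 1)
      data.frame(pos = pos, ref = ref, alt = alt, af_true = f,
                 af = f, af_binom = af_binom,
                 tumor_depth = td, normal_depth = nd,
                 filter = "PASS", normal_af = 0,
                 stringsAsFactors = FALSE)
    })

    for (ci in seq_along(config$callers)) {
      caller <- names(config$callers)[ci]
      calls <- derive_caller_calls(
        master, config$callers[[caller]], caller, config$f_min,
        config$read_depth, genome_len, config$exact_af,
        seed = child_seed(config$seed, 1000L + i * 10L + ci))
      write_caller_vcf(calls, caller, ids[i],
                       file.path(out_dir, paste0(ids[i], ".", caller,
                                                 ".vcf")))
    }
  }

  write_seg(profiles, file.path(out_dir, "cohort.seg"))

  # survival coupled to standardized true CNV dispersion
  sv <- config$survival
  z <- as.numeric(scale(truth$wg_cnv_std))
  surv <- with_seed(child_seed(config$seed, 2L), {
    hazard <- sv$h0 * exp(sv$beta * z)
    t_event <- stats::rexp(n, rate = hazard)
    t_censor <- stats::runif(n, 0, sv$censor_max)
    data.frame(hazard = hazard,
               time = round(pmin(t_event, t_censor)) + 1,
               event = t_event <= t_censor)
  })
  truth$hazard <- surv$hazard
  truth$time_days <- surv$time
  truth$event <- surv$event
  truth$group <- ifelse(truth$sigma_c > stats::median(truth$sigma_c),
                        "high_cnv", "low_cnv")

  clinical <- data.frame(
    sample = ids,
    days_to_death = ifelse(surv$event, surv$time, NA),
    days_to_last_follow_up = ifelse(surv$event, NA, surv$time),
    vital_status = ifelse(surv$event, "Dead", "Alive"),
    histologic_diagnosis = truth$group,
    stringsAsFactors = FALSE)
  write.table(clinical, file.path(out_dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")

  # gene-level expression coupled to copy number: rpkm = base * 2^c * noise
  ex <- config$expression
  genes <- sprintf("GENE%03d", seq_len(ex$n_genes))
  expr <- with_seed(child_seed(config$seed, 3L), {
    cnv_g <- t(vapply(seq_len(n), function(i) {
      glen <- sum(as.double(profiles[[i]]$segments$length))
      gpos <- round(seq(glen / (2 * ex$n_genes), glen - 1,
                        length.out = ex$n_genes))
      v <- cnv_at_locus(profiles[[i]], rep("chr1", ex$n_genes), gpos)
      ifelse(is.na(v), 0, v)
    }, numeric(ex$n_genes)))
    # focal amplifications on top of the broad segment-level values
    amp <- matrix(stats::rbinom(n * ex$n_genes, 1, ex$amp_rate), nrow = n)
    cnv_g <- cnv_g + amp * matrix(stats::runif(n * ex$n_genes,
                                               ex$amp_gain[1],
                                               ex$amp_gain[2]), nrow = n)
    snv_g <- matrix(stats::rbinom(n * ex$n_genes, 1, ex$snv_rate),
                    nrow = n)
    rpkm <- ex$base_rpkm * 2^cnv_g *
      exp(stats::rnorm(n * ex$n_genes, 0, ex$noise_sdlog))
    dimnames(cnv_g) <- dimnames(snv_g) <- dimnames(rpkm) <-
      list(ids, genes)
    list(rpkm = rpkm, cnv = cnv_g, snv = snv_g)
  })
  write_matrix_tsv <- function(m, path) {
    df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_matrix_tsv(round(expr$rpkm, 4), file.path(out_dir, "rpkm.tsv"))
  write_matrix_tsv(round(expr$cnv, 6), file.path(out_dir, "cnv_genes.tsv"))
  write_matrix_tsv(expr$snv, file.path(out_dir, "snv_genes.tsv"))

  write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(truth)
}

#' Read the truth table of a generated cohort
#'
#' @param out_dir the directory given to [generate_cohort()].
#' @return The per-sample latent-parameter `data.frame`.
#' @export
read_truth_table <- function(out_dir) {
  read.delim(file.path(out_dir, "truth.tsv"), stringsAsFactors = FALSE)
}

#' In-memory survival cohort with CNV-dispersion-coupled hazard
#'
#' Lightweight counterpart of [generate_cohort()] for power and type-I
#' error studies: per-sample copy-number profiles are generated, their
#' whole-genome CNV std is the score, and survival is exponential with
#' hazard `h0 * exp(beta * z)` on the standardized score. No files are
#' written.
#'
#' @param n cohort size.
#' @param beta log-hazard coefficient per sd of CNV dispersion.
#' @param seed integer seed.
#' @param h0 baseline daily hazard.
#' @param sigma_c_range per-sample dispersion range.
#' @param n_segments segments per profile.
#' @param censor_max upper bound of uniform censoring (days).
#' @return list with `scores` (named vector of wg CNV std) and `records`
#'   (clinical `data.frame`).
#' @export
simulate_survival_cohort <- function(n, beta, seed, h0 = 1 / 1200,
                                     sigma_c_range = c(0.05, 0.6),
                                     n_segments = 50L,
                                     censor_max = 2 * 1460) {
  ids <- sprintf("P%04d", seq_len(n))
  scores <- numeric(n)
  sigma <- with_seed(child_seed(seed, 1L),
                     stats::runif(n, sigma_c_range[1], sigma_c_range[2]))
  for (i in seq_len(n)) {
    scores[i] <- wg_cnv_std(generate_cnv_profile(
      n_segments, sigma[i], seed = child_seed(seed, 10L + i),
      sample_id = ids[i]))
  }
  names(scores) <- ids
  z <- as.numeric(scale(scores))
  records <- with_seed(child_seed(seed, 2L), {
    hazard <- h0 * exp(beta * z)
    t_event <- stats::rexp(n, rate = hazard)
    t_censor <- stats::runif(n, 0, censor_max)
    data.frame(sample_id = ids,
               time_days = pmin(t_event, t_censor),
               event = t_event <= t_censor,
               stringsAsFactors = FALSE)
  })
  list(scores = scores, records = records)
}
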