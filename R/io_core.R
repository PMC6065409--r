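#' Somatic variant call table
#'
#' Construct (and validate) a table of somatic SNV calls. Each row is one
#' call with tumor/normal allele frequencies and read depths, the VCF FILTER
#' status and the caller dialect it came from.
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt reference and alternative bases (alt may be a comma list
#'   at multiallelic sites).
#' @param tumor_af,normal_af allele fractions in `[0, 1]`.
#' @param tumor_depth,normal_depth read depths (non-negative).
#' @param filter_status VCF FILTER column text.
#' @param caller dialect tag: `"mutect"`, `"somaticsniper"` or `"varscan"`.
#' @return A `data.frame` with class `variant_calls`.
#' @export
variant_calls <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          tumor_af = numeric(), normal_af = numeric(),
                          tumor_depth = integer(), normal_depth = integer(),
                          filter_status = character(),
                          caller = character()) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    tumor_af = as.numeric(tumor_af), normal_af = as.numeric(normal_af),
    tumor_depth = as.integer(tumor_depth),
    normal_depth = as.integer(normal_depth),
    filter_status = as.character(filter_status),
    caller = as.character(caller),
    stringsAsFactors = FALSE
  )
  validate_variant_calls(df)
  class(df) <- c("variant_calls", "data.frame")
  df
}

validate_variant_calls <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  stopifnot(
    all(df$pos >= 1L),
    all(df$tumor_af >= 0 & df$tumor_af <= 1),
    all(df$normal_af >= 0 & df$normal_af <= 1),
    all(df$tumor_depth >= 0L), all(df$normal_depth >= 0L)
  )
  bad <- !df$caller %in% c("mutect", "somaticsniper", "varscan")
  if (any(bad)) stop("unknown caller dialect: ", unique(df$caller[bad])[1])
  invisible(df)
}

#' Per-sample allele-frequency set
#'
#' The unit of all heterogeneity scoring: the post-filter tumor allele
#' frequencies of one sample under one caller, with their genomic loci.
#'
#' @param sample_id sample identifier.
#' @param afs numeric vector of tumor allele frequencies.
#' @param loci `data.frame` with columns `chrom`, `pos` matching `afs`
#'   (may be `NULL` for model-generated AF sets).
#' @param cohort cancer-type tag.
#' @param caller dialect tag.
#' @param purity optional tumor purity in `[0, 1]`.
#' @return An object of class `af_sample`.
#' @export
af_sample <- function(sample_id, afs, loci = NULL, cohort = NA_character_,
                      caller = NA_character_, purity = NA_real_) {
  afs <- as.numeric(afs)
  if (!is.null(loci)) {
    loci <- as.data.frame(loci)
    stopifnot(all(c("chrom", "pos") %in% names(loci)))
    if (nrow(loci) != length(afs))
      stop("afs and loci must have the same length")
  }
  if (!is.na(purity) && (purity < 0 || purity > 1))
    stop("purity must lie in [0, 1]")
  structure(
    list(sample_id = sample_id, cohort = cohort, caller = caller,
         afs = afs, loci = loci, purity = purity),
    class = "af_sample"
  )
}

#' @export
print.af_sample <- function(x, ...) {
  cat(sprintf("<af_sample> %s [%s/%s]: %d AFs%s\n", x$sample_id,
              x$cohort, x$caller, length(x$afs),
              if (is.na(x$purity)) "" else sprintf(", purity %.2f", x$purity)))
  invisible(x)
}

#' Copy-number profile of one sample
#'
#' Genomic segments carrying a log2(copy number / 2) segment mean, the
#' quantity written by SNP-array segmentation (0 = copy-neutral, positive =
#' amplification, negative = deletion). Coordinates are 1-based inclusive
#' (TCGA SEG convention), so a segment's length is `end - start + 1`.
#'
#' @param sample_id sample identifier.
#' @param segments `data.frame` with columns `chrom`, `start`, `end`,
#'   `segment_mean`.
#' @return An object of class `cnv_profile` with a `length` column added.
#' @export
cnv_profile <- function(sample_id, segments) {
  segments <- as.data.frame(segments)
  need <- c("chrom", "start", "end", "segment_mean")
  stopifnot(all(need %in% names(segments)))
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$segment_mean <- as.numeric(segments$segment_mean)
  if (nrow(segments) > 0) {
    if (any(segments$end < segments$start))
      stop("segment end precedes start")
    segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
    rownames(segments) <- NULL
    by_chr <- split(segments, segments$chrom)
    for (s in by_chr) {
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("overlapping segments within chromosome ", s$chrom[1])
    }
  }
  segments$length <- if (nrow(segments)) segments$end - segments$start + 1L else integer()
  structure(list(sample_id = sample_id, segments = segments),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> %s: %d segments, %.3g bp\n", x$sample_id,
              nrow(x$segments), sum(as.double(x$segments$length))))
  invisible(x)
}

# ---- VCF reading -----------------------------------------------------------

# Pick tumor/normal columns from a genotype matrix. Caller conventions name
# them TUMOR/NORMAL (MuTect: the BAM sample names; our dialects use
# TUMOR/NORMAL); fall back to "first = normal, second = tumor".
tn_columns <- function(cols) {
  lc <- tolower(cols)
  tu <- which(lc %in% c("tumor", "tumour", "primary"))
  no <- which(lc == "normal")
  if (length(tu) == 1 && length(no) == 1) return(c(normal = no, tumor = tu))
  if (length(cols) < 2) stop("VCF must contain tumor and normal sample columns")
  c(normal = 1L, tumor = 2L)
}

# "25%" / "25.00%" -> 0.25; the trailing % is required for the VarScan dialect.
parse_percent <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & grepl("%$", x)
  out[ok] <- as.numeric(sub("%$", "", x[ok])) / 100
  out
}

# Comma-separated numeric FORMAT payloads summed (multiallelic sites count
# all alternative alleles together).
sum_csv_numeric <- function(x) {
  vapply(strsplit(ifelse(is.na(x), "", x), ","), function(p) {
    if (!length(p) || identical(p, "")) return(NA_real_)
    sum(as.numeric(p))
  }, numeric(1))
}

#' Read somatic SNV calls from a caller VCF
#'
#' Extracts per-record tumor and normal allele frequencies and read depths
#' from the FORMAT field, using the conventions of the declared caller
#' dialect: MuTect-like files report an allele-fraction field (`FA`),
#' VarScan-like files a percentage string (`FREQ`), and SomaticSniper-like
#' files forward/reverse reference and alternative read counts (`DP4`) from
#' which AF = alt / (ref + alt). Multiallelic sites are treated like
#' biallelic ones: all alternative alleles are pooled into one frequency.
#'
#' @param path VCF file (plain or gzip).
#' @param caller dialect tag: `"mutect"`, `"somaticsniper"` or `"varscan"`.
#' @return A [variant_calls()] table, one row per VCF record.
#' @export
read_vcf_calls <- function(path, caller = c("mutect", "somaticsniper", "varscan")) {
  caller <- match.arg(caller)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single record drops to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0) return(variant_calls())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  tn <- tn_columns(colnames(gt)[-1])

  extract <- function(element) {
    m <- vcfR::extract.gt(vcf, element = element, as.numeric = FALSE)
    if (is.null(m)) {
      m <- matrix(NA_character_, nrow(fix), 2)
    } else {
      m <- m[, tn, drop = FALSE]
    }
    colnames(m) <- names(tn)
    m
  }

  dp <- extract("DP")
  depth_n <- suppressWarnings(as.integer(dp[, "normal"]))
  depth_t <- suppressWarnings(as.integer(dp[, "tumor"]))

  if (caller == "mutect") {
    fa <- extract("FA")
    af_t <- sum_csv_numeric(fa[, "tumor"])
    af_n <- sum_csv_numeric(fa[, "normal"])
    missing_fmt <- is.na(af_t) | is.na(af_n)
    fmt_name <- "FA"
  } else if (caller == "varscan") {
    fq <- extract("FREQ")
    af_t <- parse_percent(fq[, "tumor"])
    af_n <- parse_percent(fq[, "normal"])
    missing_fmt <- is.na(af_t) | is.na(af_n)
    fmt_name <- "FREQ"
  } else {
    d4 <- extract("DP4")
    af_from_dp4 <- function(x) {
      vapply(strsplit(ifelse(is.na(x), "", x), ","), function(p) {
        if (length(p) != 4) return(NA_real_)
        p <- as.numeric(p)
        tot <- sum(p)
        if (tot == 0) return(0)
        (p[3] + p[4]) / tot
      }, numeric(1))
    }
    af_t <- af_from_dp4(d4[, "tumor"])
    af_n <- af_from_dp4(d4[, "normal"])
    missing_fmt <- is.na(af_t) | is.na(af_n)
    fmt_name <- "DP4"
  }
  if (any(missing_fmt)) {
    stop(sprintf("record %d: missing %s FORMAT field required for the %s dialect",
                 which(missing_fmt)[1], fmt_name, caller))
  }
  if (any(is.na(depth_t) | is.na(depth_n))) {
    stop(sprintf("record %d: missing DP FORMAT field",
                 which(is.na(depth_t) | is.na(depth_n))[1]))
  }

  variant_calls(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    tumor_af = pmin(pmax(af_t, 0), 1), normal_af = pmin(pmax(af_n, 0), 1),
    tumor_depth = depth_t, normal_depth = depth_n,
    filter_status = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
    caller = caller
  )
}

#' Post-call filters for somatic SNVs
#'
#' Applies the postprocessing rules that turn raw caller output into the
#' analyzable somatic SNV set: (a) for the MuTect and VarScan dialects only
#' records with `FILTER = PASS` are kept (SomaticSniper's FILTER is ignored),
#' (b) the normal allele frequency must be exactly zero and the tumor allele
#' frequency non-zero, (c) both tumor and normal read depth must reach
#' `min_depth`, and (d) allele frequencies below `min_af` are discarded
#' (vacuous on the normal side given (b), checked for generality).
#' The filter is idempotent and purely row-selecting.
#'
#' @param calls a [variant_calls()] table.
#' @param min_depth minimum read depth required of both samples (default 50).
#' @param min_af minimum measurable allele frequency (default 0.1).
#' @return The surviving subset, same class and column layout.
#' @export
apply_postprocessing_filters <- function(calls, min_depth = 50, min_af = 0.1) {
  if (nrow(calls) == 0) return(calls)
  needs_pass <- calls$caller %in% c("mutect", "varscan")
  keep <- (!needs_pass | calls$filter_status == "PASS") &
    calls$normal_af == 0 & calls$tumor_af > 0 &
    calls$tumor_depth >= min_depth & calls$normal_depth >= min_depth &
    calls$tumor_af >= min_af
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse filtered calls into a per-sample AF set
#'
#' @param calls filtered [variant_calls()] for one sample.
#' @param sample_id,cohort,purity sample annotations.
#' @return An [af_sample()].
#' @export
calls_to_af_sample <- function(calls, sample_id, cohort = NA_character_,
                               purity = NA_real_) {
  af_sample(sample_id,
            afs = calls$tumor_af,
            loci = data.frame(chrom = calls$chrom, pos = calls$pos,
                              stringsAsFactors = FALSE),
            cohort = cohort,
            caller = if (nrow(calls)) calls$caller[1] else NA_character_,
            purity = purity)
}

# ---- SEG / clinical --------------------------------------------------------

#' Read a SEG-format copy-number file
#'
#' Tab-separated with columns Sample, Chromosome, Start, End, optionally
#' Num_Probes, and Segment_Mean (matched loosely by name). Segment means are
#' taken verbatim as log2(copy number / 2) ratios. Coordinates are 1-based
#' inclusive. Returns one profile per sample.
#'
#' @param path SEG file (plain or gzip).
#' @return A named list of [cnv_profile()] objects, one per sample.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 5) stop("SEG file needs at least 5 tab-separated columns")
  nm <- tolower(gsub("[^a-z]", "", tolower(names(df))))
  pick <- function(cands, fallback) {
    i <- which(nm %in% cands)
    if (length(i)) i[1] else fallback
  }
  i_sample <- pick(c("sample", "sampleid", "id"), 1L)
  i_chrom <- pick(c("chromosome", "chrom", "chr"), 2L)
  i_start <- pick(c("start", "locstart"), 3L)
  i_end <- pick(c("end", "locend"), 4L)
  i_mean <- pick(c("segmentmean", "segmean"), ncol(df))
  start <- suppressWarnings(as.integer(df[[i_start]]))
  end <- suppressWarnings(as.integer(df[[i_end]]))
  segmean <- suppressWarnings(as.numeric(df[[i_mean]]))
  bad <- which(is.na(start) | is.na(end) | is.na(segmean))
  if (length(bad)) stop("malformed SEG row at line ", bad[1] + 1L)
  seg <- data.frame(sample = as.character(df[[i_sample]]),
                    chrom = as.character(df[[i_chrom]]),
                    start = start, end = end, segment_mean = segmean,
                    stringsAsFactors = FALSE)
  lapply(split(seg, seg$sample), function(s)
    cnv_profile(s$sample[1], s[c("chrom", "start", "end", "segment_mean")]))
}

#' Write copy-number profiles to a SEG file
#'
#' Inverse of [read_seg()]; segment means round-trip bit-exactly (written
#' with full precision).
#'
#' @param profiles a [cnv_profile()] or list of them.
#' @param path output path.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "cnv_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    s <- p$segments
    data.frame(Sample = p$sample_id, Chromosome = s$chrom, Start = s$start,
               End = s$end, Num_Probes = pmax(1L, s$length %/% 1000L),
               Segment_Mean = sprintf("%.17g", s$segment_mean),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Segment mean at a genomic locus
#'
#' @param profile a [cnv_profile()].
#' @param chrom,pos locus; both bounds of a segment are inclusive.
#' @return The covering segment's mean, or `NA` if the locus is uncovered.
#'   Vectorized over `chrom`/`pos`.
#' @export
cnv_at_locus <- function(profile, chrom, pos) {
  s <- profile$segments
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sc <- s[s$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (!nrow(sc)) next
    # segments are sorted and non-overlapping; findInterval on starts
    j <- findInterval(pos[idx], sc$start)
    hit <- j >= 1 & pos[idx] <= sc$end[pmax(j, 1)]
    out[idx[hit]] <- sc$segment_mean[j[hit]]
  }
  out
}

#' Read clinical survival data
#'
#' TSV with columns `sample`, `days_to_death`, `days_to_last_follow_up` and
#' `vital_status`. Survival time is days-to-death where present, otherwise
#' days-to-last-follow-up; the event flag is set when the vital status
#' indicates death and a death time exists. Rows lacking both time fields
#' are skipped (counted in a warning).
#'
#' @param path TSV file (plain or gzip).
#' @return `data.frame` with columns `sample_id`, `time_days`, `event`, plus
#'   any extra input columns carried through as covariates.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  col <- function(x) df[[which(nm == x)[1]]]
  stopifnot(all(c("sample", "days_to_death", "days_to_last_follow_up",
                  "vital_status") %in% nm))
  dd <- suppressWarnings(as.numeric(col("days_to_death")))
  dl <- suppressWarnings(as.numeric(col("days_to_last_follow_up")))
  dead <- grepl("dead|deceased", tolower(as.character(col("vital_status"))))
  time <- ifelse(!is.na(dd), dd, dl)
  event <- dead & !is.na(dd)
  skip <- is.na(time)
  if (any(skip))
    warning(sum(skip), " clinical record(s) without any survival time skipped")
  extra <- setdiff(seq_along(df),
                   vapply(c("sample", "days_to_death", "days_to_last_follow_up",
                            "vital_status"), function(x) which(nm == x)[1],
                          integer(1)))
  out <- data.frame(sample_id = as.character(col("sample"))[!skip],
                    time_days = time[!skip], event = event[!skip],
                    stringsAsFactors = FALSE)
  if (length(extra)) out <- cbind(out, df[!skip, extra, drop = FALSE])
  if (any(out$time_days < 0)) stop("negative survival time")
  rownames(out) <- NULL
  out
}

#' Drop low-purity samples
#'
#' @param samples list of [af_sample()] objects.
#' @param min_purity retention threshold (default 0.8); samples without a
#'   purity annotation pass with a warning.
#' @return The retained sublist.
#' @export
filter_by_purity <- function(samples, min_purity = 0.8) {
  pur <- vapply(samples, function(s) s$purity, numeric(1))
  if (any(is.na(pur)))
    warning(sum(is.na(pur)), " sample(s) without purity retained")
  samples[is.na(pur) | pur >= min_purity]
}
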