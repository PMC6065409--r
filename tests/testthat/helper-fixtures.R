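# Hand-built VCF text for one tumor/normal pair in a given caller dialect.
# `rows` is a data.frame with chrom, pos, ref, alt, filter, and the
# dialect's FORMAT payloads for normal and tumor.
toy_vcf <- function(caller, rows, path = tempfile(fileext = ".vcf")) {
  fmt_line <- switch(caller,
    mutect = "GT:FA:DP",
    varscan = "GT:FREQ:DP",
    somaticsniper = "GT:DP:DP4")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=FA,Number=A,Type=Float,Description="Allele fraction">',
    '##FORMAT=<ID=FREQ,Number=1,Type=String,Description="Percent frequency">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=DP4,Number=4,Type=Integer,Description="Read counts">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR")
  body <- if (nrow(rows)) sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\t%s\t%s\t%s",
                 rows$chrom, rows$pos, rows$ref, rows$alt, rows$filter,
                 fmt_line, rows$normal, rows$tumor) else character()
  writeLines(c(header, body), path)
  path
}

# Independent 1-D optimal-transport oracle on a chain of bins: greedy
# two-pointer mass moving, cost = mass * bins moved. Deliberately a
# different algorithm from the cumulative-difference form under test.
transport_emd_oracle <- function(f1, f2) {
  supply <- f1
  demand <- f2
  cost <- 0
  i <- 1; j <- 1
  n <- length(f1)
  while (i <= n && j <= n) {
    if (supply[i] <= 1e-15) { i <- i + 1; next }
    if (demand[j] <= 1e-15) { j <- j + 1; next }
    m <- min(supply[i], demand[j])
    cost <- cost + m * abs(i - j)
    supply[i] <- supply[i] - m
    demand[j] <- demand[j] - m
  }
  cost
}

random_histogram <- function(n_bins) {
  x <- stats::rexp(n_bins)
  structure(list(bin_width = 1 / n_bins,
                 breaks = seq(0, 1, length.out = n_bins + 1),
                 abundances = x / sum(x)),
            class = "af_histogram")
}

# Direct product-limit estimator over risk sets (independent of survfit).
km_oracle <- function(time, event, at) {
  tt <- sort(unique(time[event]))
  s <- 1
  for (u in tt[tt <= at]) {
    d <- sum(time == u & event)
    r <- sum(time >= u)
    s <- s * (1 - d / r)
  }
  s
}

# Per-base brute-force whole-genome CNV std for small profiles.
per_base_cnv_std <- function(profile) {
  vals <- unlist(lapply(seq_len(nrow(profile$segments)), function(i) {
    s <- profile$segments[i, ]
    rep(s$segment_mean, s$end - s$start + 1)
  }))
  sqrt(mean((vals - mean(vals))^2))
}

seg_text <- function(rows, path = tempfile(fileext = ".seg")) {
  df <- data.frame(Sample = rows$sample, Chromosome = rows$chrom,
                   Start = rows$start, End = rows$end,
                   Num_Probes = rep(10L, nrow(rows)),
                   Segment_Mean = rows$segment_mean)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
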