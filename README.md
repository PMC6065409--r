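# hetrobust

Tools for asking a blunt question of tumor-heterogeneity genomics: **how
much of what an allele-frequency-based heterogeneity score measures is
subclonal structure, how much is the mutation caller, and how much is copy
number?**

Bulk tumor sequencing gives each sample a set of somatic SNVs with mutant
allele frequencies (AFs). The MATH score,

```
MATH = 100 × (1.4826 × median(|x − median(x)|)) / median(x),
```

summarizes the width of that AF distribution and has been proposed as a
prognostic heterogeneity measure. But the AF distribution itself depends on
which caller produced the calls, and AFs are distorted by copy-number state.
`hetrobust` implements the analysis chain needed to study all three layers:

* **Call-set handling** — parsers for three somatic-caller VCF dialects
  (MuTect-like `FA`, VarScan-like `FREQ` percent strings,
  SomaticSniper-like `DP4` read counts), plus the postprocessing filters
  (PASS where applicable, normal AF exactly 0, depth ≥ 50 in both samples,
  tumor AF ≥ 0.1).
* **Distribution comparison** — earth mover's distance on 0.025-wide AF
  histograms in the 1-D transport (chain) form, Kolmogorov–Smirnov tests
  with per-pair Bonferroni summaries, integrated absolute KDE difference
  (σ = 0.02) and an L2 KDE permutation test (bandwidth 0.05, 100
  permutations).
* **Heterogeneity and CNV scores** — MATH (also applicable to CCF vectors),
  AF standard deviation, CNV dispersion at mutated loci, and the
  genome-length-weighted whole-genome CNV standard deviation
  `sqrt(Σ pᵢ(cᵢ − c̄)²)`, `pᵢ = lᵢ/Σlⱼ`.
* **Survival** — median-split Kaplan–Meier / log-rank analysis capped at 4
  years (1460 days), the signed normalized survival-difference integral
  `(1/T)∫[S_high − S_low]dt ∈ [−1, 1]`, and Benjamini–Hochberg correction
  across the cohort × caller grid.
* **Expression categories** — the positive-element averaging operator
  applied to masked RPKM matrices (amplified-with-SNV, not-amplified-no-SNV,
  amplified-no-SNV; thresholds 0.1 / 1.0 in log2 copy-ratio units) with
  paired Wilcoxon comparisons.
* **A linear tumor-evolution model** — clonal mutations at AF 0.5 plus a
  1/f neutral tail above `f_min`, inverse-CDF sampling, Gaussian read noise
  `N(f, f(1−f)/N)`, a closed-form MATH score
  `148.26 × B(w, f_min)`, and the demonstration that sweep timings
  `(t1, t2)` with equal neutral fraction `w = 2^t2/(t1 + 2^t2)` are
  indistinguishable to MATH.
* **A synthetic cohort generator** — deterministic, seed-driven VCF/SEG/
  clinical/expression fixtures with the statistical couplings the analysis
  assumes (caller disagreement about loci but not AFs, CNV-driven AF
  dispersion, CNV-dispersion-coupled survival hazard), so every stage runs
  and is testable at desk scale without protected patient data.

See the methods vignette (`vignettes/heterogeneity-robustness.Rmd`) for the
model details, parameter defaults, and the generator's scope.

## Worked example

Generate a 60-sample synthetic cohort and run the full study:

```r
library(hetrobust)

dir <- tempfile("cohort")
truth <- generate_cohort(cohort_config(n_samples = 60, seed = 42), dir)

calls <- read_vcf_calls(file.path(dir, "SYNTH-001.mutect.vcf"), "mutect")
nrow(calls)                                   # 183 raw records
calls <- apply_postprocessing_filters(calls)  # 169 survive the filters
s <- calls_to_af_sample(calls, "SYNTH-001")
profiles <- read_seg(file.path(dir, "cohort.seg"))
heterogeneity_scores(s, profiles[["SYNTH-001"]])
#>  sample_id caller math af_std cnv_std wg_cnv_std n_snvs
#>  SYNTH-001 mutect 55.8 0.2191   0.604     0.5577    169

res <- run_study(run_config(dir, tempfile("out"), seed = 1))
res$survival[, c("caller", "score_name", "logrank_p", "survival_difference",
                 "significant_bh")]
#>         caller score_name logrank_p survival_difference significant_bh
#>         mutect    cnv_std  3.66e-06              -0.466           TRUE
#>  somaticsniper    cnv_std  3.66e-06              -0.466           TRUE
#>        varscan    cnv_std  9.62e-06              -0.450           TRUE
#>         mutect       math  3.58e-04              -0.382           TRUE
#>  somaticsniper       math  5.45e-02              -0.215          FALSE
#>        varscan       math  3.45e-03              -0.317           TRUE
#>         mutect wg_cnv_std  3.66e-06              -0.466           TRUE
#>  somaticsniper wg_cnv_std  3.66e-06              -0.466           TRUE
#>        varscan wg_cnv_std  3.66e-06              -0.466           TRUE
```

Reading the output: this cohort plants its survival hazard on copy-number
dispersion, and the analysis recovers exactly that structure — the CNV
standard-deviation scores are significant after BH correction for **every**
caller (negative survival difference: high dispersion, worse survival),
while MATH, which sees copy number only indirectly through AFs, is
significant for two callers and misses for the third. The correlation table
makes the mediation visible (`cor(cnv_std, af_std)` ≈ 0.77 for all three
callers), and the expression comparison shows amplified-and-mutated genes
over-expressed relative to unaltered genes (fraction 1.00,
p = 5.6e-07) but not relative to amplified-without-SNV genes
(fraction 0.58, p = 0.13) — mutation status adds little on top of
amplification.

On the model side:

```r
math_closed_form(0.8, f_min = 0.1)            # 61.4113
math_score(sample_afs(evo_model_params(0.8), n = 1e5, seed = 2))
#> 61.69  (Monte-Carlo agrees with the closed form)
math_closed_form(0.3, f_min = 0.1)            # 0 — clonal regime
degeneracy_surface(0:10, 0:6)                 # equal w ⇒ identical MATH
```

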