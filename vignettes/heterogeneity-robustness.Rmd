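---
title: "Methods: allele-frequency heterogeneity, its robustness, and the linear evolution model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-frequency heterogeneity, its robustness, and the linear evolution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetrobust)
```

## The scientific problem

Bulk tumor sequencing yields, per sample, a set of somatic single-nucleotide
variants with mutant allele frequencies (AFs). The shape of the AF
distribution is widely used as a proxy for intratumoral heterogeneity, most
commonly through the MATH score — but both the distribution and any score on
it depend on which mutation caller produced the calls, and AFs are also
shaped by copy-number state, not only by subclonal structure. This package
implements the full analysis chain needed to study those dependencies at
desk scale: call-set parsing and filtering, statistical distances between AF
distributions, heterogeneity and copy-number dispersion scores, median-split
survival analysis, an expression-category operator, a linear tumor-evolution
model with a closed-form MATH score, and a synthetic cohort generator that
stands in for protected patient data.

## From VCF to an allele-frequency sample

Three caller dialects are parsed from the FORMAT field: a MuTect-like
allele-fraction field (`FA`), a VarScan-like percentage string (`FREQ`,
`"25%"` or `"25.00%"`), and SomaticSniper-like read counts (`DP4`), from
which AF = alt/(ref + alt). Multiallelic sites pool all alternative alleles
into one frequency. The postprocessing filter keeps records with

* `FILTER = PASS` — enforced for the MuTect and VarScan dialects only;
  the SomaticSniper dialect's FILTER column is ignored because that caller's
  confidence is carried by its somatic-score threshold upstream;
* normal AF exactly 0 and tumor AF > 0 (parsing yields exact zeros, so no
  epsilon is involved);
* tumor and normal read depth ≥ 50;
* tumor AF ≥ 0.1 — the minimum measurable frequency `f_min`, which also
  anchors the evolution model below.

The filter is idempotent and purely row-selecting. Note that a literal
"tumor **or normal** AF below 0.1 is discarded" rule would contradict the
normal-AF-zero requirement and empty every call set; the normal-side
condition is therefore vacuous by construction and only the tumor side is
active.

## Statistical distances between AF distributions

AFs are binned on $[0,1]$ into half-open bins of width 0.025 (the last bin
closed at 1; a $10^{-12}$ epsilon keeps boundary values such as 0.3 in their
nominal bin despite floating-point division). Between two normalized
histograms $f_1, f_2$ with $N$ bins the earth mover's distance is computed
in the chain form

$$\mathrm{EMD}(f_1,f_2) = \sum_{i=1}^{N-1}\Bigl|\sum_{j\le i} (f_{1,j}-f_{2,j})\Bigr|,$$

the one-dimensional optimal-transport cost in units of bins. The absolute
value sits **outside** the inner sum: the inside-abs reading is not a
transport cost (for $[0.5,0,0.5]$ vs $[0,1,0]$ it gives 2 where the optimal
transport moves half a unit of mass from each side to the middle for a cost
of 1). The implementation is verified in the test suite against an
independent greedy transport oracle on random histogram pairs.

Three further comparisons are provided: the two-sample Kolmogorov–Smirnov
test (asymptotic p-values by default; the exact small-sample null can be
requested for $n < 30$), the integrated absolute difference of Gaussian
kernel density estimates (kernel sd 0.02, 1001-point uniform grid on
$[0,1]$, trapezoid rule, no boundary correction — values approach 2 for
fully separated interior clusters), and a permutation test on the integrated
squared KDE difference (bandwidth 0.05, 100 label permutations). The
permutation p-value is the literal fraction of permuted statistics at least
as extreme as the observed one; ties count as extreme, so identical inputs
give $p = 1$ rather than 0, and an add-one-corrected variant is available
off by default. The kernel matrix over pooled values is computed once, so
each permutation reduces to a single matrix product; the test is
deterministic given its seed.

Cohort summaries report, per caller pair, the fraction of samples whose KS
p-value falls below the Bonferroni threshold $\alpha/m$ with $m$ the number
of per-sample tests for that pair, plus cohort medians of the EMD and KDE
distances.

## Heterogeneity and copy-number dispersion scores

$$\mathrm{MATH} = 100 \times \frac{1.4826 \times
\mathrm{median}(|x - \mathrm{median}(x)|)}{\mathrm{median}(x)}$$

The 1.4826 factor is the normal-consistency constant of the scaled MAD (and
is why the model's closed form carries the prefactor
$148.26 = 100 \times 1.4826$); it is exposed as an argument. MATH is
invariant to multiplying all AFs by a constant, hence nominally insensitive
to tumor purity, and accepts any non-negative score vector, so cancer-cell
fractions inferred by external tools can be scored identically.

All standard deviations in the package are population-style (denominator
$n$), for internal consistency with the length-weighted whole-genome form

$$\mathrm{WG\ CNV\ std} = \sqrt{\sum_i p_i (c_i - \bar c)^2},\qquad
p_i = \frac{l_i}{\sum_j l_j},\ \ \bar c = \sum_i p_i c_i,$$

over segments with log2 copy-ratio means $c_i$ and lengths $l_i$ — exactly
the per-base standard deviation under uniform sampling of the covered
genome, which the tests confirm by brute-force enumeration on small
profiles. The per-SNV variant takes the population std of segment means
looked up at mutated loci; SEG coordinates are 1-based inclusive
(length $= \mathrm{end} - \mathrm{start} + 1$), both segment bounds cover a
locus, and loci in coverage gaps are dropped from CNV statistics — no
imputation is defensible without probe-level data. The copy-number filter
removes SNVs whose segment satisfies $|c| > 0.2$; uncovered loci are
*retained* there under a copy-neutral assumption, with their count logged.
Overlapping segments within a chromosome are an invariant violation and an
error: segmented "nocnv"-style input should never contain them, and silently
resolving a conflict would hide corrupt input.

## Survival analysis

Follow-up is capped at 4 years = 1460 days (the horizon is inclusive: an
event at day 1460 remains an event; anything later becomes a censoring at
1460). Cohorts are split at the median of the score under study — ties go
deterministically to the low group — and compared with the log-rank test
(chi-square approximation) on Kaplan–Meier curves. Because the split uses
ranks only, results are invariant to monotone transformations of the score.

The direction of an effect is summarized by the signed normalized integral

$$\frac{1}{T_{max}}\int_0^{T_{max}} [S_{High}(t) - S_{Low}(t)]\,dt \in [-1, 1],$$

computed exactly by decomposing the interval at the union of both step
curves' jump times. The integrand is signed, not absolute: the quantity is
negative when the high-score group fares worse, positive when it fares
better, and antisymmetric under swapping the groups — an absolute integrand
could not carry that interpretation or attain the stated range.
Benjamini–Hochberg correction is applied jointly across the cohort-by-caller
grid of one score type at a time.

## Expression categories

For patients-by-genes matrices $r$ (RPKM), $c$ (log2 copy ratio) and $s$
(binary SNV status), the operator
$\mathscr{A}(x) = \sum_p x_{p,g} / \sum_p u(x_{p,g})$ averages the positive
entries of each gene column, with $u(x) = 1$ for $x > 0$ and 0 otherwise
(the printed piecewise definition puts zero in the zero branch, and that
definition is followed). Genes with no qualifying patient are discarded
(`NA`) per category. The three categories are the masked products
$r\,u(c - c_2^{th})\,s$ (amplified with SNV),
$r\,u(c_1^{th} - c)(1-s)$ (not amplified, no SNV) and
$r\,u(c - c_2^{th})(1-s)$ (amplified, no SNV), with thresholds
$c_1^{th} = 0.1$, $c_2^{th} = 1.0$; amplified and non-amplified masks are
mutually exclusive per cell. Paired comparisons report the fraction of genes
where one category exceeds the other — exact ties are excluded from the
denominator — and a Wilcoxon signed-rank p-value (exact null below 25 pairs,
tie-corrected normal approximation otherwise).

## The linear evolution model

Mutations predating the last selective sweep are clonal at AF exactly 0.5;
the fraction $w$ ("neutral fraction") arising after the sweep follows the
neutral $1/f$ tail. With $\nu = 2wf_{min}/(1-2f_{min})$ the AF distribution
is

$$P(F\le f)=\begin{cases}0, & f<f_{min},\\[2pt]
\frac{\nu}{2}\bigl(\frac{1}{f_{min}}-\frac{1}{f}\bigr), & f_{min}\le f<0.5,\\[2pt]
1, & f=0.5,\end{cases}$$

and sampling is by inverse CDF: clonal with probability $1-w$, otherwise
$f = f_{min}/(1 - u(1-2f_{min}))$ for uniform $u$. The MATH score has the
closed form

$$\mathrm{MATH} = 148.26\times\begin{cases}
0, & w \le \tfrac12,\\[2pt]
\frac{1}{2\varphi}-1, & \tfrac12 < w \le \tfrac12+\Delta w,\\[2pt]
\frac{\sqrt{\nu^2+\varphi^2}-\nu}{\varphi}, & w > \tfrac12+\Delta w,
\end{cases}$$

with $\varphi = \nu f_{min}/(\nu - f_{min})$ (the population median AF in
the neutral regime) and
$\Delta w = (\sqrt{1+32f_{min}^2}-1)/(16 f_{min})$. In the middle branch the
median absolute deviation is set by the distance from the median to the
clonal atom; beyond $\tfrac12+\Delta w$ the tail dominates. The function is
continuous at both boundaries (verified to $10^{-8}$ over a grid of
$f_{min}$) and identically zero in the clonal regime.

A property worth stating explicitly because it is easy to get wrong: the
closed form is **not monotone** in $w$ on the neutral side. At
$f_{min}=0.1$ it rises from 0 at $w=\tfrac12$ to about 93 at
$w = \tfrac12+\Delta w \approx 0.593$ and then *declines* to about 44.9 at
$w=1$:

```{r closed-form-shape}
w <- c(0.5, 0.55, 0.593, 0.7, 0.85, 1)
round(math_closed_form(w, f_min = 0.1), 2)
```

Consequently two different neutral fractions — two different evolutionary
histories — share a MATH score, and under exponential growth
($w = 2^{t_2}/(t_1 + 2^{t_2})$) a whole curve of sweep timings
$(t_1, t_2)$ maps to one score. `degeneracy_surface()` makes both layers of
this degeneracy explicit; any downstream analysis asserting a monotone
MATH–$w$ relationship would be wrong.

Sequencing noise is modeled by the Gaussian approximation to binomial read
sampling, $\mathcal{N}(f,\ f(1-f)/N)$ at depth $N$ (default 100). Draws are
clipped to $[10^{-3}, 1-10^{-3}]$ — clipping rather than resampling keeps
the draw count and the RNG stream deterministic. After noising, the
$f_{min}$ measurement cutoff is *not* re-applied by default, because
re-filtering changes the score's null behavior in the clonal regime; a
`refilter_f_min` argument enables it, so both protocols are available.
Noise lifts MATH strictly above zero in the clonal regime while barely
affecting the neutral regime.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not any real dataset: per-sample AF sets from the evolution model
(default 100–300 SNVs per sample, $w \sim U(0.3, 1)$, $f_{min} = 0.1$,
depth 100); contiguous single-chromosome copy-number profiles with 40–60
segments of 0.5–5 Mb and segment means $\mathcal{N}(0, \sigma_c)$ with
$\sigma_c \sim U(0.05, 0.6)$ per sample; caller dialects that disagree
mostly about *which* loci are called — Bernoulli retention (sensitivities
0.95/0.85/0.80 for the MuTect-, SomaticSniper- and VarScan-like dialects),
extra dropout near $f_{min}$, spiked false calls (rates 0.05/0.08/0.03) —
while AFs at shared loci differ only by read-count quantization plus a
0.01-sd jitter, keeping shared-locus correlations above 0.95; exponential
survival with hazard $h_0 e^{\beta z}$ on the cohort-standardized true
whole-genome CNV std ($h_0 = 1/1200$ per day, $\beta = 1$, uniform
administrative censoring over twice the 4-year horizon); and gene-level
expression $\mathrm{RPKM} = 10 \times 2^{c} \times$ log-normal noise, with
focal amplifications (rate 0.1, gain 1–2.5 in log2 units) planted on top of
the broad segment values so the amplification categories are populated.
AF–copy-number coupling places the mutant allele on one of the $2\cdot 2^c$
copies, so AF dispersion tracks CNV dispersion. A truth table records every
latent parameter, and regeneration under the same seed is byte-identical
(no timestamps are written).

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: subclonal copy-number mixtures, purity as a
mechanistic AF scaler (purity is annotated but does not distort AFs),
germline contamination structure, caller-specific systematic biases beyond
sensitivity/false-call/jitter, mutational signatures, and any real linkage
between expression and survival. Conclusions about real cohorts require the
real data; the generator certifies the *pipeline*, not the biology.

## Numerical and design choices

* Global seeds are fanned out to per-stage child seeds through a
  fixed affine scheme (`child_seed`), so stages rerun independently yet
  deterministically, and all randomized functions restore the caller's RNG
  state.
* Median-split ties go to the low group; all-equal scores are an error
  (no split exists).
* The KS test's asymptotic null is the default at cohort scale; the exact
  null is available for small samples.
* `w = 0` makes $\nu = 0$; the intermediates guard the $0/0$ in $\varphi$
  and the closed form returns 0 through the clonal branch.
* Degenerate inputs error early with informative messages (empty AF
  vectors, zero medians, mismatched binning, overlapping segments,
  non-positive horizons).
* Problem sizes in the test suite: Monte-Carlo agreement of the closed form
  uses 25 replicates of $10^5$ draws per $w$ (the single-replicate sample
  median is too noisy near the branch peak for a 1-unit check); transport
  and per-base oracles use 200–225 random cases; survival power and
  calibration use cohorts of 200 over 100 planted-effect seeds and 500 null
  seeds; pipeline round-trips use 12-sample cohorts.

## Known limitations

* The evolution model is one scenario — linear sweeps with constant
  mutation rate after the last sweep and genotype–phenotype decoupling;
  branching or punctuated dynamics, rate changes after the sweep, and
  CNV–model interactions are out of scope.
* Cancer-cell-fraction inference is not performed; CCF vectors are only
  accepted as score inputs.
* The auxiliary statistics battery is a configurable default chosen here
  (moments, quantiles, histogram entropy, bimodality, near-clonal mass),
  not a canonical set.
* Log-rank uses the chi-square approximation; very small cohorts would
  warrant an exact test.
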