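Package: hetrobust
Title: Robustness of Allele-Frequency-Based Tumor Heterogeneity Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how intratumor heterogeneity estimates derived
    from mutant allele frequency distributions depend on the mutation-calling
    pipeline, and how they relate to copy-number dispersion and patient
    survival. Implements MATH scoring (scaled MAD over median of tumor allele
    frequencies), earth mover's distance and kernel-density comparisons of
    allele-frequency distributions between caller dialects, genome-length
    weighted copy-number standard deviations, median-split Kaplan-Meier /
    log-rank survival analysis with a signed normalized survival-difference
    integral, an expression-category averaging operator for
    amplification/SNV comparisons, and a linear tumor-evolution model with a
    closed-form MATH score, sequencing-noise model and evolutionary-history
    degeneracy demonstration. A deterministic synthetic-cohort generator
    emits caller-dialect VCFs, SEG copy-number segments, clinical and
    expression tables with the statistical structure the analysis assumes,
    so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
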