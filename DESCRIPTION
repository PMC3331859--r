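Package: poolgwas
Title: Pooled-DNA Allelotyping Genome-Wide Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for case-control genome-wide association
    studies run on pooled DNA samples. Computes relative allele signal (RAS)
    from two-channel array intensities, averages technical replicates,
    excludes aberrant pools by principal-component screening, and tests
    group allele-frequency differences with Student's t-tests and
    one-degree-of-freedom chi-square tests. Candidate markers are selected
    by LD-proxy clumping, validated and replicated on individual genotypes
    with missingness and Hardy-Weinberg quality control, allelic and
    logistic-regression (additive/dominant/recessive) association,
    Benjamini-Hochberg correction, DerSimonian-Laird random-effects
    meta-analysis with Cochran's Q and I-squared heterogeneity, and
    analytic two-proportion power calculations. Includes a synthetic-cohort
    generator emulating equimolar 15-sample pools measured in technical
    triplicate, blockwise linkage disequilibrium, and configurable
    genotyping error, so the whole pipeline is testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
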