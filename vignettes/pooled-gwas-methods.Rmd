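---
title: "Statistical methods behind poolgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind poolgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolgwas)
```

# The problem

Genotyping every subject of a case-control cohort on genome-wide SNP
arrays is costly. Pooling equimolar amounts of DNA from groups of
subjects (here 15 per pool) and hybridizing each pool to one array
estimates *group* allele frequencies at a fraction of the cost: the
pooled stage acts as a variance filter, and only its candidate markers
are genotyped individually for validation and replication. The price
is extra technical variance — pool construction, array hybridization —
which the statistics below are designed around. `poolgwas` implements
the full chain and ships a generator that simulates cohorts with the
exact structure the chain assumes, so each stage is verifiable against
planted truth.

# Pooled stage

## Relative allele signal

For SNP $j$, pool $i$, replicate $r$, with channel intensities $A$ and
$B$, the relative allele signal is $\mathrm{RAS} = A/(A+B)$. RAS is
scale-invariant in the channels, lies in $[0,1]$, and for a noiseless
equimolar pool equals the pool's allele-A frequency exactly. Replicates
(default 3 per pool) are averaged arithmetically; a pool × SNP cell
needs at least `min_replicates = 2` usable replicates, otherwise it is
missing. Entries with $A + B \le 0$ are missing and counted in a QC
report; negative intensities are an input error, not data.

## Pool exclusion

Aberrant pools (degraded DNA, poor hybridization) shift RAS across many
SNPs at once, so they separate on the leading principal components of
the column-centred pool × SNP matrix. Because a visual call is not
reproducible, the filter is algorithmic: a pool is excluded when its
PC1 or PC2 coordinate has a robust z-score
$|x - \mathrm{median}| / (1.4826\,\mathrm{MAD}) > 3.5$. One pass only —
no iterative re-fitting — so the rule is deterministic and cannot
cascade. Missing cells are imputed with the per-SNP mean *for the
decomposition only*; downstream tests see only observed values. With
fewer than 3 pools the filter refuses and passes everything through
with a warning; a zero-variance matrix excludes nothing.

## Dual association test

Two tests are run per SNP and both must pass selection:

* **Student's t-test** (equal variance, $df = n_1 + n_2 - 2$) on
  pool-level mean RAS. It respects between-pool variation, the dominant
  nuisance in pooled designs, but loses power when pools are few.
* **1-df Pearson χ²** on the 2×2 table of *continuous* allele counts
  $(\bar{R}_1 \cdot 2N_1,\; (1-\bar{R}_1)\cdot 2N_1;\;
  \bar{R}_2 \cdot 2N_2,\; (1-\bar{R}_2)\cdot 2N_2)$, no continuity
  correction. Counts are not rounded — rounding would make results
  depend on pool-size parity. $N_g$ counts only subjects represented by
  non-missing pools at that SNP, so missingness cannot fabricate
  alleles.

Degenerate cases: both groups zero-variance with equal means gives
$p_t = 1$; zero variance with unequal means is marked untestable
(the t statistic is infinite and meaningless); fewer than two usable
pools in either group is untestable.

# Clump selection

Candidates must be locally corroborated: an index SNP significant at
$p < 10^{-3}$ under *both* tests forms a clump only if some distinct
same-chromosome SNP within 100 kb has $r^2 > 0.7$ with it (strict
inequality) and χ² $p < 10^{-3}$. Indices are processed greedily in
ascending χ² p (ties: position, then id), and every SNP belongs to at
most one clump. $r^2$ is the squared Pearson correlation of unphased
dosages in a reference panel (composite LD — no phasing needed);
monomorphic markers and pairs with fewer than 10 complete observations
get $r^2 = 0$. The "both tests" index rule is the conservative reading
of combining the two statistics; a `chi2`-only rule is available via
`clump_config(index_rule = "chi2")`. The 100-kb window is interpreted
as index-proxy distance ≤ 100,000 bp. The greedy selection is verified
in the tests against a brute-force enumeration oracle on panels of up
to 200 SNPs.

# Individual genotyping

QC runs in a fixed order, single pass: drop SNPs with missingness
≥ 0.05, then individuals with missingness ≥ 0.05 (computed on the
surviving SNPs), then SNPs with control-group Hardy-Weinberg exact
$p < 10^{-3}$. Thresholds are exclusive for keeping, matching their
"< 0.05" phrasing. The HWE test is the exact conditional test — the
p-value sums the probabilities of all heterozygote counts no more
probable than the observed one given the allele counts — evaluated
through log-gamma so totals up to $10^5$ are stable.

The allelic test fixes the minor allele in the control group and keeps
that orientation across comparisons. The odds ratio is the 2×2
cross-product; its 95% CI uses the log-OR normal approximation with
$SE = \sqrt{1/a + 1/b + 1/c + 1/d}$, adding Haldane's 0.5 to every cell
only when some cell is zero. Logistic models code genotype as dosage
(additive), carrier (dominant) or minor-homozygote (recessive) and are
fit by IRLS (`stats::glm`); $|\beta| > 15$ or non-convergence is
treated as separation and no p-value is reported. Benjamini–Hochberg
correction is applied within each (comparison, model) family,
mirroring per-table corrected columns. A pooled candidate is
*confirmed* when the individual allelic test has $p < 0.01$ and the
same odds-ratio direction as the pooled stage.

The case-only onset scan dichotomizes age at diagnosis at 65 years
(≤ 65 coded 1), a convention exposed via `cutoff_years`, and fits all
three codings with BH correction across the scan.

# Meta-analysis

Cochran's $Q = \sum w_i(\theta_i - \bar\theta_{FE})^2$ with
$w_i = 1/se_i^2$; $I^2 = \max(0, (Q - (k-1))/Q) \times 100$ (0 when
$Q = 0$). The DerSimonian–Laird moment estimator
$\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\big)$
re-weights studies by $1/(se_i^2 + \tau^2)$; the pooled log OR is
their weighted mean, with $SE = 1/\sqrt{\sum w^*}$ and a two-sided Z
test. DL is used because it is the historical default of the standard
meta commands; REML is not implemented. When a study supplies a CI
instead of an SE, $se = (\ln \mathrm{ci_{high}} -
\ln \mathrm{ci_{low}})/(2 \times 1.96)$ — note the recovered bounds
then re-centre on the point estimate, so they match the input only up
to its log-asymmetry. The implementation is cross-checked against an
independent package on random instances to $10^{-10}$.

# Power

The two-proportion normal-approximation power treats the allele
frequency as a per-subject proportion (`counting = "subjects"`), with
$p_1 = \mathrm{OR}\,p_0/(1 + p_0(\mathrm{OR}-1))$:
$$\mathrm{power} = \Phi\!\Big(\frac{|p_1-p_0| - z_{\alpha/2} SE_0}{SE_1}\Big)
 + \Phi\!\Big(\frac{-|p_1-p_0| - z_{\alpha/2} SE_0}{SE_1}\Big),$$
with $SE_0$ at the pooled frequency and $SE_1$ at the alternative. The
second tail is numerically zero for any real effect but makes the null
value equal $\alpha$ exactly. Per-subject counting (not per-allele) is
the default because it reproduces the standard design-power figures
for this cohort size; allele counting doubles effective n and is
available. Note power is *not* monotone in $p_0$ at fixed OR: for
OR = 2 with 630/690 subjects at $\alpha = 10^{-3}$ it rises from 98.6%
at $p_0 = 0.2$ to a maximum of 99.9% at $p_0 = 0.4$ and eases to 99.8%
at 0.5.

# The synthetic generator

What it emulates, and the defaults that define the simulated study:

* **Genotypes.** HWE at the control MAF; case frequency
  $F_1 = \mathrm{OR}\,F_2/(1 + F_2(\mathrm{OR}-1))$, a direct
  frequency-shift parameterization chosen over a liability-threshold
  model because the analyses report allelic ORs, making recovery checks
  exact.
* **LD.** Fixed-length blocks (default 5 SNPs) share one MAF and OR;
  haplotypes copy the left-neighbour allele with fidelity
  $c = \sqrt{r^2_{\mathrm{target}}}$, else redraw, so adjacent-marker
  allele correlation is $c$ and dosage $r^2$ hits the target while
  marginals are preserved exactly. Proxy SNPs therefore exist by
  construction; across blocks markers are independent.
* **Pools.** Phenotype-homogeneous, 15 subjects, chunked in manifest
  order; leftovers logged. Pool frequency is the equimolar mean of
  member dosages over $2 \times 15$ (exactly), or Dirichlet-weighted if
  a finite pooling concentration models unequal contributions.
* **Intensities.** Channel A expectation $\mathrm{gain} \cdot f +
  \mathrm{background}$, channel B the complement, with independent
  multiplicative log-normal noise of CV 0.05 by default — a
  one-parameter noise model sufficient to exercise the t-test/χ²
  trade-off; probe chemistry and cross-hybridization are deliberately
  not modelled. At these defaults the measurement noise inflates the
  pooled χ² variance by about 1%, so its nominal calibration holds.
* **Aberrant pools.** A frequency-scale shift of +0.1 before intensity
  generation, an intentionally simple stand-in for unmodelled DNA
  quality/hybridization failures.
* **Degradation.** Entry-wise missingness, dosage-step genotyping
  errors within {0,1,2}, and optional SNPs with heterozygosity inflated
  1.5× (renormalized) so the HWE filter has true positives.

Everything is a pure function of (specification, seed); one master
seed fans out to per-stage child seeds. What the generator does *not*
emulate — population stratification, batch effects across arrays,
differential missingness, X-chromosome male dosages (all markers are
autosomal-style) — bounds what green tests prove: they certify the
statistics and their calibration under the assumed design, not
robustness to confounding that the original workflow also did not
correct for.

# Problem sizes and numerical choices

The packaged demonstration uses 2,000 SNPs, ten planted OR-2.0 blocks
at MAF 0.3, 630 + 690 subjects pooled 15-at-a-time in triplicate, and
an 800 + 800 replication cohort — sizes chosen so a full run takes a
few seconds while every stage still has near-unit power for its
planted signals. Calibration checks use 2,000-marker null panels;
outlier-pool detection is assessed over 100 seeded 5,000-marker runs;
clumping is verified against enumeration on ≤ 200-marker panels.

Tolerances: exact-arithmetic identities (cross-product OR, brute-force
χ², enumerated HWE) are asserted to $10^{-9}$–$10^{-12}$; IRLS
convergence uses `epsilon = 1e-10` with at most 100 iterations;
the HWE tie rule counts outcomes with probability within a $10^{-9}$
relative margin of the observed one as "no more probable".

# Known limitations

* The pooled χ² treats mean RAS as if it were a frequency measured
  without technical error; with many replicates and low noise CV the
  approximation is good (~1% variance inflation at defaults) but it is
  anti-conservative for noisy designs with few replicates.
* PCA exclusion is single-pass by design; two simultaneous aberrant
  pools that mask each other on PC1/PC2 may survive.
* The power formula is asymptotic; no exact binomial option.
* VCF support is GT-only and biallelic; multi-allelic records are
  skipped with a warning.
* Reproducing published per-marker discovery counts requires the
  original patient data; the tests instead verify the statistical
  properties those counts depend on.
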