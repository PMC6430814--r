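---
title: "Detecting allele-specific RNA-binding protein binding in eCLIP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific RNA-binding protein binding in eCLIP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asbind)
library(dplyr)
```

## The problem

A heterozygous single-nucleotide variant (SNV) inside an RNA-binding
protein's (RBP) binding site exposes two slightly different substrates to
the same protein in the same cell. If the protein binds one allele more
strongly, reads from an eCLIP experiment pile up unevenly on the two
alleles — allele-specific binding (ASB). Detecting ASB from read counts is
harder than it looks, for two reasons this package addresses head-on:

1. **Crosslinking bias.** UV crosslinking stalls reverse transcription at
   the protein-RNA contact, and it does so preferentially at uridines. The
   sequence context around a crosslink site therefore distorts allelic read
   counts in a way that depends on the *allele base itself* — exactly the
   quantity being compared.
2. **Overdispersion.** Allelic counts vary between biological replicates far
   more than binomial or Poisson sampling admits. Tests that combine
   replicates and assume binomial noise (chi-square, Fisher's exact test)
   hand out ever smaller p-values as coverage grows, flooding high-coverage
   sites with false positives.

## The model

### Crosslink-bias normalisation

Crosslink sites are called inside each peak as positions where the number
of read-2 5' ends, $m_i$, exceeds what uniform placement of the peak's
reads would produce (empirical permutation FDR $\le$ 0.001, 1000
permutations by default). From the crosslink sites of the *size-matched
input* (SMInput) — where no specific RBP is enriched, so the base
composition reflects crosslinking chemistry alone — the package tabulates
$q(a, d)$: the relative frequency of base $a$ at offset
$d \in [-25, 25]$ from the site. The raw count $y_{i,a,j}$ of allele $a$ at
SNV $i$ in replicate $j$ is then corrected to

$$x_{i,a,j} = \frac{y_{i,a,j}}{q(a, d)\, R_j},$$

where $R_j$ is the replicate's usable reads in millions and $d$ the
strand-oriented offset of the SNV to its nearest crosslink site. Outside
the window ($|d| > 25$, or no site in the peak) $q$ is the neutral 0.25,
reducing the correction to per-million scaling. A propensity of exactly
zero (a base never seen at an offset in a finite SMInput sample) is floored
at 0.005 with a warning rather than treated as a true impossibility.

### Variance moderation

With $k = 2$ replicates the per-SNV sample variance is hopeless as an
estimator. Instead, for every allele of every testable SNV the package
computes the mean $\mu$ and squared coefficient of variation
$\omega = \sigma^2/\mu^2$ of its normalised counts across replicates, and
fits a LOESS regression of $\omega$ on $\log_2 \mu$ pooled over the whole
experiment. The moderated variance of an allele with mean $\mu$ is
$\hat\sigma^2 = \hat\omega(\log_2\mu)\,\mu^2$. Predictions are clamped to
the training range of $\log_2 \mu$ and floored at $10^{-6}$ so the test
statistic below is always defined.

### The imbalance test

At each SNV the allele with the larger mean normalised count is the major
allele $M$, the other the minor allele $m$. Under a flat prior the
posterior for the generating mean of $M$ given its $k$ observations is
$\mathcal{N}(\mu_M, \hat\sigma_M^2 / k)$, and the two-sided p-value is
twice the posterior mass at or below the minor mean:

$$p = 2\,\Phi\!\left(\frac{\mu_m - \mu_M}{\sqrt{\hat\sigma_M^2/k}}\right),$$

capped at 1 (a tie gives exactly 1, with the reference allele kept as major
for determinism). Benjamini-Hochberg adjustment is applied across all
testable SNVs of one experiment, and events are called at FDR < 10%.

### Posterior filters

On real data six stepwise filters remove candidate artifacts, in this
order: homopolymer runs ($\ge$ 5 identical reference bases containing the
SNV), annotated microsatellites (half-open interval overlap), mappability
($\ge$ 95% best off-target identity of the 101-mer centred on the SNV, via
a pluggable precomputed table), allele-specific *expression* (genes whose
testable SNVs are all biased at binomial-test BH FDR < 0.05 in at least
two RNA-Seq data sets, with all reference ratios outside 40-60%),
reference-mapping bias (candidate ratio within one SD of the bulk SMInput
ratio distribution), and multi-RBP hotspots (2-kb windows where positions
shared by more than four RBPs exceed a Poisson background at BH FDR <
0.01). Each filter is a pure predicate; the chain reports per-step
attrition and a candidate failing several filters is counted at the first.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| peak enrichment fold | 4 (inclusive) | eCLIP peaks must be $\ge$4-fold library-normalised over SMInput in $\ge$1 replicate |
| crosslink site FDR | 0.001 | permutation FDR ceiling for a called site |
| bias window | $\pm$25 nt | extent of measurable sequence propensity around the crosslink |
| propensity floor | 0.005 | guards against finite-sample zeros in $q$ |
| het coverage / ratio | 10, [0.25, 0.75] | SMInput evidence for a bi-allelic site |
| base quality | $\ge$10 | per-base pileup filter |
| LOESS span / degree | 0.75 / 1 | smooth, local-linear mean-CV² trend; both configurable |
| CV² floor | $10^{-6}$ | keeps $\hat\sigma^2 > 0$ |
| ASB FDR | < 0.10 | significance threshold on BH-adjusted p-values |
| testability | total $\ge$ 10 per replicate | below this the allelic ratio is too unstable for any method |

## What the simulator emulates — and what it does not

`simulate_asb_study()` generates per-SNV, per-replicate allelic counts
with the statistical structure the test has to survive:

* one total coverage per SNV, drawn from an empirical distribution when
  supplied, otherwise log-normal with median ≈ 55 and log-SD 1 (a shape
  typical of coverage at SNVs inside eCLIP peaks). Coverage is shared by
  the replicates, so replicate-to-replicate spread comes entirely from the
  count noise — matching how the between-replicate variance is specified.
  An option (`shared_coverage = FALSE`) redraws coverage per replicate
  instead;
* allelic counts from a zero-truncated negative binomial with mean $rC$
  (major) and $(1-r)C$ (minor) and variance `default_var_target()`
  $= m + 0.05\,m^2$: Poisson noise plus an overdispersion term whose CV²
  plateau of 0.05 mimics the high-count asymptote of real replicate
  trends. Truncation is by exact rejection; at these means the acceptance
  probability is high, so rejection costs nothing and introduces no
  approximation;
* 10% of SNVs carry true ASB at major ratio $r \in \{0.7, 0.8, 0.9\}$
  (0.8 in the shipped benchmarks), the rest are null at $r = 0.5$;
* optional multiplicative crosslink bias from `synthetic_bias_table()`,
  whose T propensity $0.25 + 0.30\,e^{-|d|/4}$ peaks at ~0.55 over the
  crosslink and decays to neutral — the uridine-enrichment shape seen in
  SMInput data. Every allele count is rescaled by $q(a,d)/0.25$, rounded,
  floored at 1; this is exactly the transformation the normalisation
  inverts, up to rounding.

The simulator does **not** emulate read-level artifacts: mapping bias
toward the reference allele, PCR duplication structure, peak-calling
uncertainty, multi-allelic sites, or correlated noise between alleles of
one SNV beyond the shared coverage. Passing benchmarks on this generator
therefore demonstrate the statistical properties of the test (bias
correction, variance moderation, overdispersion robustness), not immunity
to alignment artifacts — that is what the posterior filters are for, and
they are exercised on constructed micro-fixtures instead.

## Benchmarks and the problem sizes used

The shipped benchmark (`benchmark_asb_methods()`, also re-run by
`scripts/acceptance.R`) uses 100 experiments of 5000 SNVs each, with and
without injected bias — enough that the win fraction and mean PR-AUC are
stable to well under the margins being asserted, while one run stays in
the minutes range. Comparator tests combine replicate counts: the
chi-square test is the 1-df goodness-of-fit against a 50/50 split without
continuity correction; Fisher's exact test contrasts the observed counts
with a balanced table of the same total (the 2×2 construction is not
uniquely determined by the comparison being mimicked; this choice affects
the comparator only). Performance is summarised as PR-AUC (prevalence is
10%, so precision-recall is more informative than ROC), sensitivity at
95% specificity, specificity at 95% sensitivity, and the percentage of
calls per coverage bin.

## Numerical and design choices

* **Sample variance** uses the unbiased $k-1$ denominator; with $k = 2$
  this is the squared half-difference times two.
* **Major-allele assignment** uses normalised counts (the test operates
  entirely on the normalised scale); exact ties resolve to the reference
  allele.
* **Offset resolution** when a peak holds several crosslink sites: the
  nearest site wins, with ties broken toward the 5' site. The choice is
  ours; no rule is forced by the data model.
* **BH families** are per experiment (events are reported per RBP/cell);
  pooling across experiments is a one-line change for users who prefer a
  global family.
* **Fisher p-values** are computed by direct hypergeometric tail
  summation (a probability-ordered two-sided rule, the same convention as
  `stats::fisher.test`, against which the implementation is tested to
  1e-12) because the benchmark calls it millions of times.
* **LOESS smoothing bias**: the default span of 0.75 with local-linear
  fits flattens sharply curved trends; on a synthetic $\omega = 1/\mu$
  response a span of 0.5 tracks the curve within 15% while 0.75 can err
  by ~25% near the boundaries. The default favours stability on real,
  gently varying trends; narrow the span when the fitted curve visibly
  underfits `tidy(trend)` diagnostics.

## Known limitations

* **Null calibration is approximate by construction.** The test compares
  $\mu_m$ against the posterior of the *major* allele's mean only; the
  sampling noise of $\mu_m$ itself is not propagated. Under the null the
  difference of two allele means has variance $2\sigma^2/k$, not
  $\sigma^2/k$, so the z-score is inflated by $\sqrt{2}$ and the p-value
  distribution on all-null simulations is measurably non-uniform (the
  acceptance script reports a Kolmogorov-Smirnov distance of ~0.13 from
  U(0,1) at 5000 testable SNVs). In the far tail this inflation is far
  too small to survive BH at realistic scales — the same script reports
  0% of null SNVs called at FDR < 10% — and rankings (hence PR-AUC) are
  unaffected, but the raw p-values should not be treated as exactly
  uniform under the null.
* The empirical Gaussian is a large-count approximation; at the
  testability floor (total 10 per replicate) normalised counts are small
  and the Gaussian tail is only a rough guide. The stable per-bin call
  rates in the benchmark show the moderation keeps this under control.
* Only bi-allelic SNVs are modelled, matching the major/minor test
  structure; indels and multi-allelic sites are out of scope.
* Base Alignment Quality is taken as the qualities stored in the BAM;
  if upstream realignment wrote BAQ-adjusted values they are honoured,
  but the package does not recompute BAQ itself.
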