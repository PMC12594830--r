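---
title: "Methods: quantifying the labile cysteine S-acetylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the labile cysteine S-acetylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thioacetylome)
```

## The measurement problem

Cysteine S-acetylation attaches an acetyl group (+42.011 Da, monoisotopic)
to a cysteine thiol through a thioester bond. Unlike the amide bond of
acetyl-lysine, a thioester is cleaved by dithiothreitol (DTT), hydrolyzes
above neutral pH, and migrates between free thiols, so the modification
survives only specialized sample preparation (TCEP as reducing agent, pH at
or below 7, immediate alkylation of free cysteines). Downstream of the mass
spectrometer, the analysis receives label-free peptide-level quantification
tables: one row per unique peptide with protein accession(s), a
modification-site annotation string such as `[C150(50); C154(50)]` or the
ambiguous `[K/C411]`, a PSM count, and per-sample normalized abundances,
accompanied by protein-level rollups and a sample design (group, biological
block, covariates such as reducing agent or acetyl-CoA dose).

This package implements that downstream analysis. Throughout, an
"acetyl-cysteine peptide" is any peptide carrying at least one acetyl site
on C or on an ambiguous K/C pair — ambiguous sites are counted as cysteine
candidates because localization between an adjacent lysine and cysteine is
frequently uncertain at the spectrum level. Missing abundance is distinct
from zero; zero intensities are converted to missing on read, since an MS1
intensity scale has no true zeros.

## Differential abundance model

**Normalization.** For each peptide–protein pair and sample, the analysis
value is the ratio of peptide abundance to protein abundance; peptides
mapping to several proteins become separate analytes per assignment. The
ratio removes protein-expression differences, so a contrast on the ratio
reflects a change in modification stoichiometry rather than in protein
amount. Analytes whose ratio is exactly 1.0 in every sample (tolerance
`1e-9`) arise when a protein is quantified by that single peptide; they are
uninformative on the ratio scale and are analyzed separately on their
original peptide abundances. Both parts are log2-transformed. Analytes
missing in at least half the samples of any group are excluded from
fitting; no imputation is performed, and log2 of missing stays missing.

**Blocking.** Technical or paired samples from the same biological source
are modeled through a single consensus within-block correlation shared by
all analytes. Per analyte, residuals after removing group means are formed;
within-block pairs of residuals give a per-analyte correlation (mean pair
product over mean squared residual), and the consensus is the tanh of the
10%-trimmed mean of atanh values, clipped to (−0.99, 0.99). Negative values
are allowed — real acetylome data produce small negative consensus
correlations — and designs without replicated blocks fall back to zero with
a warning. This moment-style estimator is simpler than per-analyte REML and
is approximately unbiased for paired designs (one sample per group per
block), which is the structure the presets generate; strongly unbalanced
block designs would need the REML machinery and are a known limitation.

**Moderated statistics.** Each analyte is fit by least squares after
whitening with the equicorrelated within-block covariance implied by the
consensus correlation (Cholesky of the block-diagonal correlation matrix
restricted to observed samples); with correlation zero this reproduces
ordinary least squares exactly. Residual variances $s^2$ with $d$ residual
degrees of freedom are shrunk toward a prior: the prior degrees of freedom
$d_0$ and prior variance $s_0^2$ are estimated from the marginal
distribution of $\log s^2$ by matching its mean and excess variance over
the theoretical $\operatorname{trigamma}(d/2)$ contribution, inverting the
trigamma by Newton iteration. The posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and the moderated
$t = \log_2\!\mathrm{FC}/(\mathrm{SE}\cdot\tilde s)$ on $d + d_0$ degrees
of freedom. One numerical choice deserves note: when the moment estimate of
the between-analyte variance of $\log s^2$ is non-positive, the prior
degrees of freedom are infinite and $s_0^2$ is set to the *geometric mean*
of the sample variances rather than a bias-corrected value, so that
analytes with identical variances shrink to themselves and the moderated t
equals the ordinary t exactly in that degenerate case. In the regular case
the estimator coincides with the standard moment solution, and the test
suite verifies exact agreement of coefficients, t, p and prior degrees of
freedom with an independent reference implementation at a shared
correlation. Analytes with fewer than two residual degrees of freedom
receive no p-value.

**Multiplicity.** BH step-up adjustment is applied once per contrast across
the concatenation of variant and non-variant parts, over analytes that
received a p-value.

## Site classifiers

**Lability.** On the TCEP-vs-DTT contrast, a site is significant when
$|\log_2 \mathrm{FC}| \ge \log_2(\text{fc\_cutoff})$ and adjusted
$p < \alpha$ (defaults 2-fold and 0.05, the conventional volcano cutoffs);
significant sites are `tcep_labile` (higher with TCEP — ablated by DTT, the
thioester signature) or `dtt_up`. The summary is the percent of significant
sites labeled `tcep_labile`, rounded to a whole percent and undefined when
nothing is significant.

**Dose response.** Sites respond to acetyl-CoA titration in qualitatively
different ways; the literature describes these classes verbally, so the
numeric boundaries here are this package's choices, exposed as parameters:
with fold changes $FC_1, FC_{10}$ relative to control,

* `unresponsive` if $\max(FC_1, FC_{10}) < 2$ (`min_fold`);
* `saturable` if $FC_1 \ge 0.8\,FC_{10}$ (`saturation_ratio`) and
  $FC_1 \ge 2$ — near-maximal response already at the low dose;
* `threshold` if $FC_1 < 1.5$ (`threshold_low`) and $FC_{10} \ge 2$ —
  all-or-nothing behaviour;
* `linear` otherwise.

The rule is an if-else cascade, so the classes partition the positive-fold
plane. The three canonical exemplars — catalase-like (3.0, 3.3),
glutamate-dehydrogenase-like (4.5, 36) and GAPDH-like (1.0, 15) — are fixed
as regression tests for the saturable, linear and threshold classes.

## Enrichment

Peptide statistics are aggregated to proteins as the arithmetic mean of
moderated t over an analyte's protein assignments. Overrepresentation uses
the one-sided hypergeometric tail of the foreground against the identified
background, with gene sets intersected with the background first and BH
across sets; the test suite checks the p-values against an explicit
binomial-coefficient tail summation to 1e-12. Preranked GSEA computes the
weighted Kolmogorov–Smirnov running sum (increments proportional to
$|t|^{w}$ inside the set, $-1/(N-K)$ outside; the score is the extreme
deviation) and a *gene-set* permutation null: random same-size sets, with
$p = (1 + \#\{|ES_0| \ge |ES|\})/(n_{\mathrm{perm}}+1)$ — bounded below by
$1/(n_{\mathrm{perm}}+1)$ — and $NES = ES / \overline{|ES_0|}$ over
same-sign null scores. At the default 10,000 permutations the attainable p
floor is about $10^{-4}$, sufficient for hallmark-scale collections;
multilevel refinement for smaller p-values is deliberately out of scope.
Tied statistics are broken by a deterministic order-based jitter far below
the statistic's resolution.

## Multivariate summaries

PCA operates on samples with features centered and scaled across samples
(sample sd, $n-1$); rows with any missing value are dropped first
(complete-case), constant features are dropped with a warning, and
component signs follow the convention that each component's
largest-magnitude loading is positive. Variance explained is reported over
all components and sums to one. Peptide-level PCA is run on
peptide-to-protein normalized values, so sample separation reflects
modification changes rather than protein abundance. Hierarchical
clustering uses one minus Pearson correlation (range [0, 2], scale-free in
the rows) with average linkage; zero-variance rows are dropped with a
warning. Heatmap z-scores use the sample-sd convention; constant rows
become zero.

## The synthetic generator

The generator emulates the statistical structure each stage assumes, not
the spectra: log2-normal peptide intensities (base level $2^{N(20, 1.5^2)}$
by default — an LFQ-like spread over several orders of magnitude),
acetyl-cysteine peptides as a low-stoichiometry subpopulation (by default
5% of the parent protein's remaining peptide signal), protein abundance as
the per-sample sum of member peptides, multiplicative group effects,
independent log-normal residual noise, paired or per-sample blocks, and
missingness injected completely at random. Intensity-dependent missingness,
retention-time structure and acetyl-transfer scrambling kinetics are
deliberately not modeled, so passing tests demonstrate estimator
correctness under the stated error model, not robustness to those
real-data features.

Two injection conventions matter. Reducing-agent (lability) effects are
injected on the *ratio* scale: because the protein rollup is the sum of its
peptides, a raw peptide multiplier is solved analytically per site
($x = RC/(C + b(1-R))$ for sibling sum $C$, acetyl base $b$, target ratio
fold $R$) so the zero-noise pipeline recovers the injected log2FC exactly.
Dose-titration effects are injected on the raw intensity scale, matching
how per-site fold changes are reported.

The presets fix the study conditions:

* `dtt_ablation` — 300 acetyl-C sites, 267 labile at +2 log2FC (TCEP over
  DTT) and 33 at −1.2, residual sd 0.4, n = 3 per arm, paired liver
  blocks, 5% missingness, seed 1. Eight peptides per protein and a
  base-intensity log2 sd of 1.0 keep the protein denominator stable, so
  essentially all sites reach adjusted-p significance; the share of
  significant sites called TCEP-labile is then governed by the −1.2 class's
  proximity to the 2-fold cutoff and lands near 89–92%.
* `acoa_dose` — 100 baseline sites plus 13 induced at 1 mM and 47 more at
  10 mM (exact 13% / 60% unique-site expansions); the common stoichiometry
  multiplier of non-exemplar baseline sites is solved so the normalized
  summed acetyl intensity rises exactly 3.7-fold and 8.6-fold; three
  exemplar sites carry the canonical per-site folds. Defaults: residual sd
  0.3, 2% missingness; noise-free mode (`residual_sd = 0, missing_rate =
  0`) makes every recovery exact.
* `fractionation` — three compartments with site-membership marginals
  392/249/237 and a three-way intersection of exactly 87 (region sizes
  195/62/60 unique, 60/50/40 pairwise-only; the pairwise-only sizes are
  this package's choice, the marginals and triple are the anchored
  quantities). Per-fraction intensity levels 2/1/0.7 make the supernatant
  the most acetylated compartment.
* `cold_bat` — two temperature groups, n = 3, one (unreplicated) block per
  animal, 100 of 200 sites loading on a single latent component with
  loadings in ±[0.75, 2.25] log2 units, emulating a coordinated acetylome
  shift that a PCA separates along its first component.
* `smoke` — 20 peptides, for end-to-end smoke tests.

Where the underlying study reports no noise magnitudes or replicate CVs,
the preset residual sds (0.3–0.4 log2 units, i.e. ~20–30% CV) are chosen
once as typical label-free peptide-level variability; they are scenario
parameters, not tuning knobs. Every preset is deterministic under its seed,
and all randomness in a scenario flows from that single seed (the
quantification stage derives its stream from it by a fixed offset).

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale: the largest
simulated experiments are 1,000–2,450 peptides across 6–9 samples,
Monte-Carlo checks use 1,000–2,000 analytes, and GSEA calibration uses 150
replicates of 200 permutations. A full pipeline run on the `dtt_ablation`
preset takes a few seconds. Pipeline outputs are plain TSV files written at
fixed precision, and rerunning with the same config and seed is
bit-identical; the run log records the package version, seed, stages and
effective thresholds (2-fold change, p < 0.05, 10,000 permutations by
default).

## Known limitations

The consensus-correlation estimator targets paired block designs; the
generator's missingness is completely at random; protein rollups are plain
sums (no top-n or maxLFQ-style summarization); GSEA p-values are bounded by
the permutation count; and unknown-position sites participate only in
peptide-level, not positional, statistics.
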