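---
title: "Methods: life-history fitness scoring and heat-stress expression analysis"
author: "tardistress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: life-history fitness scoring and heat-stress expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tardistress)
```

`tardistress` analyses temperature-gradient experiments on individually
reared tardigrades — microscopic meiofaunal animals whose Antarctic
populations face steadily warming habitats. The package covers two linked
questions: how rearing temperature and generation shape life-history traits
and a composite fitness score of individually followed females, and how a
gradual temperature increase (5 °C control, then 10, 15, 20 °C, each
sampled after 1 day of exposure, "ST", and after 15 days, "LT") reshapes
the transcriptome of pooled animals. Everything downstream of gene-level
count quantification is implemented here; read processing, assembly and
quantification are out of scope.

Because per-female raw records and raw reads of any particular experiment
are not shipped, every stage is validated against synthetic data with
planted ground truth. This vignette documents the models, the tunable
parameters, the design choices made where the design was genuinely open,
and what the synthetic validation does and does not show about real data.

## Life-history model

A female's record is her rearing metadata (generation P/F1/F2, rearing
temperature, life span in days, number of molts) plus an ordered list of
clutches; a clutch is an oviposition day, eggs laid, eggs hatched, and one
hatching time (days from oviposition) per hatched egg. Days are integers
with day 0 = birth. Invariants are enforced at construction: hatched ≤
laid, strictly increasing oviposition days, no oviposition after death.

`derive_traits()` computes one row per female: fecundity (total eggs
laid), number of ovipositions, mean inter-oviposition interval, age at
first oviposition, mean hatching time, total hatched eggs, and hatching
percentage. Three aggregation choices were open and are fixed as follows:

* the inter-oviposition *interval* is the **mean** of successive
  differences of oviposition days (a median alternative is available via
  `interval_aggregator`);
* a female's *hatching time* is the **mean** over her hatched eggs;
* *hatching percentage* is 100 × total hatched / fecundity per female;
  females that never laid get a missing value, **never** an imputed 0 —
  undefined traits stay `NA` throughout and are excluded, not guessed.

## The fitness score

Fitness of a female is the mean of four components normalized to [0, 1]
over the scored pool. Traits where more is fitter use min–max
normalization,

$$x' = \frac{x - \min x}{\max x - \min x},$$

applied to fecundity and total hatched eggs; traits where less is fitter
(mean hatching time, age at first oviposition) use the inverted form
$x' = 1 - (x - \min x)/(\max x - \min x)$. Hatched eggs being the
prerequisite for contributing to future generations, a **zero rule**
precedes the mean: a female that never laid, or none of whose eggs
hatched, scores exactly 0.

Two points were genuinely open:

* **Normalization pool.** Scores are compared across generation ×
  temperature groups on one scale, so the default pool is *all scored
  females together*; `pool = "per-temperature"` rescales within each
  rearing temperature instead. Nothing in the score itself can
  disambiguate the two conventions — they simply answer different
  questions ("fittest overall" vs. "fittest for her temperature").
* **Degenerate bounds.** When a trait takes a single value across the
  pool (max = min) it carries no ranking information; the component is set
  to the neutral 0.5 rather than forcing 0 or 1. Zero-rule females still
  contribute their (defined) zeros to the fecundity and hatched-egg
  bounds but never to hatch-time or age bounds, which are undefined for
  them.

## Cohort statistics

`fit_trait_glm()` fits each trait against generation, temperature, and
their interaction (clutch-level models use oviposition order and clutch
size), with reference levels generation P (F1 when no parental females are
in the data) and the lowest temperature. Families are not dictated by the
trait names alone, so `family = "auto"` assigns by response support:

| response type | family | note |
|---|---|---|
| durations (life span, intervals, ages, hatch time) | gaussian-identity | |
| counts (molts, ovipositions, fecundity, clutch size) | poisson-log | upgraded to negative-binomial-log when the Pearson dispersion exceeds 1.5 |
| hatching percentage | binomial-logit | weighted by eggs behind each percentage |

Confidence intervals and p-values use the Wald z approximation (estimate
± 1.96 SE on the link scale). This is asymptotic: with ten or fewer
females per cell the ignored t correction costs a couple of points of
coverage, which is why the package's own coverage checks use twenty and
more per cell. `standardized_coefficients()` refits after centring and
scaling numeric predictors — and, for gaussian models only, the response;
count and proportion likelihoods need the original response, so there only
the predictors are standardized.

Fitness scores are compared among groups with the Kruskal–Wallis test
(midranks, standard tie correction, χ² approximation with k − 1 df). The
post-hoc routine behind published letter groupings is typically
unreported; here it is pairwise Wilcoxon rank-sum tests with Bonferroni
(default) or Holm adjustment.

## Expression post-processing

The chain assumes a genes × samples matrix of non-negative counts and a
design table (temperature, exposure, replicate). The 5 °C group is the
control and anchors every comparison.

**CPM.** `cpm_transform()` scales each sample to counts per million;
`log = TRUE` gives log2(cpm + 1) (prior count configurable), and
`row_normalize = TRUE` subtracts row means for display.

**Contig → gene grouping.** Assembled contigs sharing the same best
protein hit (highest bitscore; ties broken by lower e-value, then
lexicographically smallest subject id, so the result is independent of
record order) collapse into one gene; contigs without hits stay singleton
genes. This removes isoform/multi-copy noise without claiming to separate
splicing isoforms from paralogs.

**Empirical controls.** The least-varying genes are found by a first-pass
all-groups omnibus test (every temperature × exposure cell its own group)
on expression-filtered genes, ranking by ascending omnibus statistic and
keeping the lowest 1000 by default. "Lowest variation" had to be
operationalized; the omnibus statistic is the natural scalar from a
first-pass differential-expression analysis.

**Unwanted variation.** `estimate_unwanted_factors()` takes the samples ×
controls matrix of gene-centred log2-cpm and returns the first *k* left
singular vectors as nuisance covariates W (unit-norm columns). Control
genes are assumed unaffected by the conditions, so shared variation among
them is technical.

**Outlier samples.** Published screening was visual (MDS/PCA plots);
`detect_outlier_samples()` replaces it with a fixed, deterministic rule:
project samples onto the first two principal components of log2-cpm and
measure each sample's distance to its *nearest group-mate*. The nearest
mate, rather than the group centroid, because with three replicates a
gross outlier drags its centroid and would implicate innocent group-mates.
A sample is flagged when its distance exceeds the median plus
`c_mad` × MAD of all within-group distances. The default `c_mad = 6` was
calibrated on homogeneous null simulations of the standard 24-sample
design so that clean experiments are flag-free about 95% of the time,
while a sample with a gross compositional shift (a 10-fold change in half
its transcriptome) sits tens of MADs beyond the cut-off. Note that a
truly *global* fold shift of every gene is absorbed by CPM normalization
and is undetectable in principle — which is why the simulator injects
compositional, not global, outliers. Samples alone in their group cannot
be assessed and are never flagged.

**Differential expression.** Per gene, a negative-binomial log-linear
model with a temperature factor (plus exposure as a blocking term when
both exposures are analysed jointly, plus the W columns) and log
library-size offsets. Dispersion is method-of-moments per gene — pooled
(variance − mean)/mean² across cells on library-size-normalized counts —
then shrunk 50/50 toward the median dispersion across genes. When W is
supplied, its per-gene log-scale contribution is regressed out *before*
the moments are taken; otherwise planted technical variation masquerades
as biological dispersion and the adjusted model gains no power. The
omnibus likelihood-ratio test of all temperature terms (an ANOVA-like
comparison of every temperature against the control) is referred to χ²
with (number of temperatures − 1) df; Benjamini–Hochberg adjustment gives
FDRs, with significance at FDR < 0.01 by default. Bit-compatibility with
any particular DE package is not targeted; the backend is validated by
planted-truth recovery and type-I error control. Genes failing the
expression filter — cpm > 1 in at least as many samples as the smallest
group (the filter rule itself being unstated in typical reports) — are
excluded and listed. A design flag (`exclude_samples`) supports dropping a
temperature group with excessive intra-replicate diversity, e.g. the
15 °C long-term samples.

**Direction.** Each gene's temperature pattern is the sign of the
least-squares slope of its per-temperature mean log2-cpm against numeric
temperature: up, down, or flat.

**Enrichment.** For each annotation term: universe N (expressed genes), K
annotated, DEG set n, overlap k; upper-tail hypergeometric p, expectation
nK/N, observed/expected ratio k/(nK/N); BH adjustment across tested terms.
A term is significant only when FDR < 0.05 **and** O/E > 3 — the ratio
threshold guards against statistically significant but biologically
trivial overlaps in large universes. Terms with K = 0 are skipped. The
enrichment universe defaults to the genes passing the expression filter in
the analysed subset.

A note on `bh_adjust()`: step-up BH adjustment is *not* idempotent —
re-adjusting an already-adjusted vector can inflate isolated small values
— so the package asserts the true properties (elementwise ≥ input, ≤ 1,
order-preserving) and not idempotence.

## Synthetic data and what it shows

All generators are pure functions of (config, seed) and restore the
caller's RNG state.

**Life-history cohorts.** Durations (life span, age at first oviposition,
intervals, hatch times) are lognormal with group-specific natural-scale
mean/SD; clutch sizes are 1 + Poisson with an order-dependent mean, so a
positive `clutch_slope` reproduces clutches growing over the life span;
eggs hatch independently with the group's hatch probability. Default
group parameters echo published anchors for an Antarctic species — first
oviposition around day 34 and hatching in about 22 days at 5 °C,
substantially shorter life spans at 15 °C — but they are configuration,
not claims about any dataset. Planted zero-fitness females (no-egg,
no-hatch) are appended to a designated group (default F2 at 15 °C);
ordinary females are conditioned on producing at least one hatched egg
(the first clutch hatches 1 + Binomial(eggs − 1, p) eggs), so the
zero-rule count downstream equals exactly the planted count.

**Expression experiments.** Default design: 4 temperatures × 2 exposures
× 3 replicate pools = 24 samples. Baseline relative abundances are
lognormal; planted DEGs (10% by default, half up, half down) shift their
log2 mean by `lfc_per_step` per 5 °C step — monotone in temperature, with
the default of one log2 unit giving 8-fold at 20 °C; counts are negative
binomial (default dispersion 0.1, library sizes uniform on 1–2 million).
Optional batch structure assigns the last replicate of every cell to a
second processing run with per-gene N(0, `batch_sd`) log2 shifts; optional
outlier samples get `outlier_fold` applied to a random half of their
genes.

Validation on these data shows planted-truth recovery, calibration, and
invariances; sizes used by the package's own checks are 2000 genes for
calibration/recovery runs, 100 seeded replicates for coverage and
flag-rate properties, and 100–120 females per cohort. What passing does
**not** show: real transcriptomes have correlated genes, gene-specific
dispersion trends, compositional biases and annotation structure that the
simulator does not emulate, and real cohorts violate lognormal/Poisson
idealizations; results on real data depend on those features. The
generators exist to prove the machinery correct, not to imitate any
organism's numbers.

## Numerical choices and degenerate inputs

* log transform: log2(cpm + 1); the prior count is a parameter.
* NB fits with dispersion below 1e-8 fall back to Poisson; a failed
  per-gene fit yields statistic 0, p = 1 (never a spurious discovery).
* A gene with identical counts in every sample (equal library sizes)
  gets p = 1.
* Grouping tie-breaks (bitscore, then e-value, then subject id) make the
  partition deterministic under record permutation.
* Identical values in every Kruskal–Wallis group give H = 0, p = 1
  (the tie-corrected formula is 0/0 there).
* Min–max with max = min maps to 0.5; values outside the bounds are an
  error, not clamped.

## Known limitations

* The DE backend's 50/50 dispersion shrinkage is deliberately simple; no
  empirical-Bayes trend or tagwise weighting.
* Wald z intervals undercover modestly in small cells; no profile or t
  intervals are offered.
* Outlier detection considers only the first two principal components.
* The fitness score is the study-style composite only; no demographic
  fitness measures (e.g. Euler–Lotka r) are computed.
* Per-exposure versus global enrichment universes remain a user choice;
  the default is the analysed subset's expressed genes.
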