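---
title: "Simulating and benchmarking synthetic bulk RNA-seq count data"
author: "countsimbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking synthetic bulk RNA-seq count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countsimbench)
```

## Motivation

Benchmarking statistical and machine-learning methods for RNA-seq requires
datasets whose multidimensional distribution is known — real data never come
with ground truth about which genes differ between conditions, how features
co-vary, or how separable the sample classes are. `countsimbench` addresses
the two halves of that problem:

1. **Generation**: a two-class bulk RNA-seq count simulator with fully
   recorded ground truth — differential-expression (DE) flags and true
   log-fold-changes, designed feature–feature correlation blocks, class and
   subgroup labels.
2. **Assessment**: a battery of criteria that quantifies how faithfully any
   synthetic count matrix (from this simulator or any third-party generator)
   reproduces an input dataset: distributional concordance, mean–dispersion
   and mean–variance structure, feature–feature correlation, DE geometry and
   class separability — with a per-criterion ranking across generators.

## The generative model

Counts arise in two stages.

**Latent concentrations.** For sample $s$ in class $k$, the vector of latent
natural-log mRNA concentrations is one multivariate-Gaussian draw
$$x_{\cdot s} \sim \mathcal N\!\left(\mu^{(k)},\; \sigma^2 R\right),$$
where $R$ is a block-structured correlation matrix: unit diagonal,
compound-symmetry blocks of size $b$ with common correlation $\rho$ on the
designated block features, zeros elsewhere. Each block is positive definite
exactly when $\rho > -1/(b-1)$ (the block spectrum is $1+(b-1)\rho$ once and
$1-\rho$ with multiplicity $b-1$); the constructor rejects anything else.
Global DE markers have
$\mu^{(2)}_g = \mu^{(1)}_g + \mathrm{lfc} \cdot \ln 2$, so the designed
effect is an exact log2 fold change on the concentration scale.
Heterogeneous markers receive the same shift only in
$\lceil K/2 \rceil$ randomly chosen class-1 subgroups out of $K$.
Because the latent scale is logarithmic, concentrations
$\exp(x_{gs})$ are automatically positive.

**Poisson reads.** Given a calibrated rate scale $a$ and per-sample depth
factors $d_s$ (uniform on a configurable interval, degenerate at 1 by
default),
$$c_{gs} \sim \mathrm{Poisson}\!\left(a\, d_s\, e^{x_{gs}}\right).$$
Marginally each count is a lognormal–Poisson mixture, i.e. overdispersed
relative to Poisson with a method-of-moments NB dispersion close to
$e^{\sigma^2}-1$ (about 0.17 at $\sigma = 0.4$, about 0.63 at
$\sigma = 0.7$); with $\sigma = 0$ the model degenerates to pure Poisson,
which the test suite uses as a calibration fixture.

**Depth calibration.** The overall mean count per matrix entry is brought to
a target (default 300 reads per feature) by a fixed-point iteration on a
pilot simulation of the same dimensions: $a \leftarrow a \cdot
\mathrm{target}/\mathrm{mean}$, with the pilot Poisson draw re-generated
from a fixed child seed each round, a 1% relative tolerance, and at most 20
iterations (non-convergence is a diagnostic error carrying the last pilot
mean). Because the Poisson mean is linear in the rate, one to two rounds
normally suffice, and doubling the target doubles the returned scale.

### Presets and defaults

Two presets encode the study conditions the package is built around:
`"ngssppg1"` (latent noise $\sigma = 0.4$, an easily separable two-class
structure) and `"ngssppg2"` ($\sigma = 0.7$, classes that mix in a PCA
embedding). Both are 10,000 features × 100 samples (50/50), 5% global DE
markers, one 5-feature correlation block at $\rho = 0.4$, mean count
calibrated to 300. `"-small"` variants (500 × 20) keep every statistical
setting and shrink only the dimensions; they are what the examples and most
tests use.

Choices the model leaves open were fixed once, as follows:

* **DE effect size** is not part of the preset description anywhere we could
  anchor it, so the default is `lfcDE = 1` (fold change 2): reliably
  detectable at 50 samples per class under $\sigma = 0.4$ yet genuinely hard
  at $\sigma = 0.7$, reproducing the intended "simple" vs "difficult"
  contrast. It is a plain parameter, configurable per run.
* **Marker counts** follow `round(deFraction * nFeatures)` (banker's
  rounding, R's `round`): 5% of 10,000 gives 500; 5% of 34,616 gives 1731.
* **Block placement**: blocks are drawn from the non-DE features so that a
  designed correlation is never confounded with a designed mean shift; the
  assignment is recorded per feature in `rowData`.
* **Depth jitter** defaults to off (`c(1, 1)`): the presets model equal
  sequencing depth, and depth variation belongs to the generators being
  benchmarked, not to the reference design.
* **Heterogeneous markers** default to zero; when requested, the shifted
  subgroups are chosen at random (recorded in `metadata`), since only the
  parameter itself — not its mechanics — is externally specified.
* **RNG**: one root seed per run; each randomized stage (marker placement,
  block placement, latent draw, depth jitter, pilot, Poisson, subsampling)
  consumes its own deterministically derived child seed, so stages are
  independently reproducible and a fixed seed yields byte-identical output.

## The assessment battery

All criteria compare an *input* dataset with a *synthetic* dataset and
scalarize into a non-negative distance; self-comparison is, by construction,
the all-zero fixed point (`assessPair(x, x)` returns exact zeros), which the
suite asserts.

**Q-Q concordance.** Five sample pairs are matched by sorted library size
(evenly spaced ranks, so the pairing is invariant to column order), each
pair compared on the `log2(count + 1)` scale at 99 equally spaced
probabilities with the type-7 (linear interpolation) quantile estimator —
the estimator is fixed and documented because Q-Q values depend on it. Per
pair we record the OLS slope and intercept through the quantile pairs, the
maximum absolute quantile deviation, and the two-sample Kolmogorov–Smirnov
statistic; the dataset-level summary is the mean over pairs.

**Dispersion and mean–variance.** The per-feature method-of-moments NB
dispersion is $\phi = \max(0, (v - m)/m^2)$ under $\mathrm{Var} = \mu +
\phi\mu^2$, with $\mathrm{BCV} = \sqrt\phi$, computed on median-of-ratios
normalized counts. The mean–dispersion trend is a running median over 20
equal-occupancy bins of log mean (quantile bins stabilize medians in sparse
mean ranges), linearly interpolated between bin centers and constant
beyond. Two datasets are compared by the median of
$\lvert\log((t_a + \delta)/(t_b + \delta))\rvert$ over a shared log-spaced
mean grid, $\delta = 10^{-3}$ guarding near-zero trends; the mean–variance
relationship is summarized and compared the same way. No empirical-Bayes
shrinkage is attempted — the diagnostic contrast (flat vs decreasing trend,
low vs high BCV) is what the framework consumes, and the gene-wise MoM
values are labelled as such.

For *testing* (below) the dispersion is instead estimated within classes
(degrees-of-freedom-weighted average of per-class MoM values): marginal
moments count the class effect under test as variance, which at small
sample sizes drives power to zero. The diagnostic keeps the marginal
convention — mean–dispersion plots are conventionally design-free — so both
variants are exposed (`estimateDispersionsMoM(x, byClass = TRUE)`).

**Correlation structure.** Up to 25 non-constant features are sampled
(seeded) per dataset, and Spearman correlations are taken for all unordered
pairs. By default values are `log2(count + 1)`-transformed and correlations
are computed within each class then averaged per pair: between-class mean
shifts otherwise inflate every correlation (the suite demonstrates this
with a constructed shift), and the choice is logged because either
convention is defensible; a pooled mode is available. The distance between
two correlation distributions is their two-sample KS statistic. For
simulated data, `blockRecovery()` contrasts the mean within-block
correlation against a matched seeded sample of off-block pairs (10× the
within-block pair count). Under the separable preset parameters the
recovered within-block Spearman correlation is slightly below the design
value 0.4 — the Gaussian-copula Spearman of a latent correlation 0.4 is
$\tfrac{6}{\pi}\arcsin(0.2) \approx 0.385$, and Poisson rank noise
attenuates mildly — landing near 0.36–0.38 at 2000 samples.

**Differential expression.** A self-contained delta-method NB Wald test
stands in for a full GLM framework: per feature, normalized class means
$m_1, m_2$ (pseudocount $\epsilon = 0.5$), $lfc = \log_2\!\frac{m_2 +
\epsilon}{m_1 + \epsilon}$, class-mean variances $v_k = (m_k + \phi
m_k^2)/n_k$ with the conservative $\phi_g = \max(\text{gene MoM},
\text{trend})$, standard error by the delta method, two-sided normal
p-value, Benjamini–Hochberg adjustment (`stats::p.adjust`; the suite checks
it against a brute-force step-up). The suite verifies a type-I error within
[0.035, 0.065] at nominal 0.05 on a null NB fixture ($\mu = 300$, $\phi =
0.1$, 50 vs 50, 5000 features). This test is deliberately *not* a
re-implementation of any published DE package: DEG counts produced by
different DE engines on the same data differ by implementation detail, so
cross-generator DEG comparisons are made with the same engine on both
datasets and only count differences at a common $\alpha$ enter the ranking
(synthetic features need not map to input features, so gene-identity
overlap is not used). Volcano classification uses p < 0.05 for
significance and |lfc| > 1 for effect size — note that published volcano
captions sometimes print the significance inequality inverted; the
convention here is the standard one. `signBalance()` reports the fraction
of significant effects that are positive, flagging
"over-expression only" generator artifacts.

**Separability.** Samples are embedded by PCA of the log2-CPM matrix (prior
0.5, all features, centered, unscaled — no top-gene preselection, with a
`topFeatures` option; component signs are fixed by making the
largest-magnitude loading positive so embeddings are deterministic). Class
separability is the mean silhouette width on (PC1, PC2) with Euclidean
distance and the known labels as clusters — a scalar proxy for what is
usually judged visually on a 2-D PCA, required here for ranking. Across
matched seeds the $\sigma = 0.4$ preset scores a strictly higher silhouette
than the $\sigma = 0.7$ preset, which the suite asserts over 5 seeds.

**Ranking.** `compareGenerators()` orders generators per criterion by
ascending distance (the DEG criterion by $|\Delta \text{DEG}|$,
separability by the absolute silhouette difference), ties broken
lexicographically by name. No aggregation into a single score is attempted:
which generator is "best" is criterion-specific by design, and the
per-criterion table *is* the result.

## Data preparation

Input datasets are prepared the standard way before assessment:
`filterZeroMedian()` drops features whose all-sample median is 0 (with
integer counts and an even sample count, the median is the midpoint of the
two central order statistics); `subsetBalanced()` draws an exact
$n$-per-class subset without replacement, seeded; `truncateOutliers()` caps
entries above a ceiling (default $10^7$) and reports how many were
truncated. Filtering and subsetting commute only approximately, so the
order used is the caller's choice and both are supported; the CLI logs the
order it ran.

## Numerical and degenerate-input choices

* Counts must be integer-valued and non-negative; validity is enforced on
  the container (`CountDataSet`, a `SummarizedExperiment` subclass), and
  file readers reject violations with line/column locations.
* Zero library sizes are errors naming the sample; an all-zero matrix is
  representable but most metrics refuse it explicitly.
* `momDispersion` clips under-dispersion to 0 (so BCV is always real), and
  a zero mean yields $\phi = 0$.
* p-values of exactly 0 are mapped to the smallest positive double before
  $-\log_{10}$, capped at 350, for volcano output.
* Degenerate Q-Q comparisons (constant quantile grid) flag an undefined
  slope rather than fabricating one.
* Poisson rates above $10^{12}$ abort with a diagnostic (overflow guard).
* All-zero-discovery sign balance is `NaN` with a warning, and recovery
  conventions are sensitivity 0 / FDR 0.

## Problem sizes used by the checks

The automated checks run the full 10,000 × 100 presets where the claim is
about the preset itself (dimensions, DE design, calibration; about a second
each on one core) and scaled-down designs everywhere the claim is a
statistical property: 500 × 20 presets for power/separability properties,
200 features × 2000 samples for block-correlation recovery, 5000 × 100 for
the type-I fixture. These sizes were chosen so each check has enough
Monte-Carlo resolution for its stated tolerance while the whole suite stays
interactive.

## What the generator does and does not emulate

The simulator reproduces the features the assessment battery measures:
calibrated mean depth, tunable overdispersion via $\sigma$, designed DE
with exact truth, compound-symmetry correlation blocks, two-class (and
subgroup) structure. It deliberately does **not** model: zero inflation or
the 10–40% sparsity typical of real bulk RNA-seq (lognormal–Poisson at mean
300 produces almost no zeros); a mean-dependent dispersion trend (real data
show decreasing trends, this model's BCV is flat in the mean — visible in
its own dispersion diagnostics); library-size heterogeneity beyond uniform
jitter; negative-binomial or zero-inflated latent models; and any
single-cell characteristics. Consequently, a generator that passes all
checks against a simulated input has been shown to reproduce *this* model's
structure; faithfulness to real tissue data must be assessed with a real
input dataset, which the toolkit accepts as plain TSV/Matrix-Market counts
plus a two-class annotation.

## Known limitations

* The NB Wald test uses a normal reference distribution; at very small
  sample sizes (fewer than ~5 per class) its type-I control degrades, and
  the suite only validates it at 50 per class.
* DEG counts are engine-specific; absolute counts from other DE tools on
  the same data will differ. Only same-engine differences are meaningful.
* The KS statistic on heavily tied (low-count) data is conservative.
* Silhouette on two PCs summarizes separability only in the leading
  principal plane; class structure confined to later components is
  invisible to it, matching the visual convention it replaces.
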