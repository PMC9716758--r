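---
title: "Quantitative, viability-aware metagenomic surveillance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative, viability-aware metagenomic surveillance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Metagenomic surveillance of built environments — hospital surfaces above
all — faces three linked problems: samples are low-biomass, sequencing does
not by itself distinguish viable from dead organisms, and read counts are
compositional, not quantitative. A fourth, practical problem precedes all of
them: nobody knows how deeply to sequence a sample before it has been
sequenced. `metasurv` implements a computational workflow that addresses
all four: absolute-abundance quantification via multi-species spike-in
internal standards or 16S qPCR totals, PMA (propidium monoazide) viability
efficacy analysis on paired treated/untreated samples, low-biomass
decision-support rules, and a two-stage model that predicts required
sequencing effort from accessible sample metadata.

This vignette explains the models, the tunable parameters, and the design
choices that were genuinely open; the README shows the worked example.

# Quantification

## Spike-in scaling

A spike-in internal standard is a community of $M$ taxa added to each sample
with known input quantities $q_m$ (cells or 16S gene copies). After
sequencing and taxonomic profiling, member $m$ receives $r_{ms}$ reads in
sample $s$, giving a per-member conversion factor $q_m / r_{ms}$
(copies/read). The sample-level factor is the **median** over members,

$$ c_s = \operatorname{median}_m \; q_m / r_{ms}, $$

and any native taxon $i$ with $r_{is}$ reads is estimated at
$\hat{a}_{is} = r_{is} \, c_s$. The median was chosen over the mean because
classifier bias concentrates on individual spike taxa (database
representation varies wildly between species); the median moves only between
neighboring order statistics when one member is off by an order of
magnitude, while the mean moves proportionally. The mean remains available
(`aggregate = "mean"`), and per-member factors are always retained for
diagnostics: a member whose factor is far from the sample median is a
classification problem, not a pipetting one.

Two structural caveats are enforced in code rather than prose. First, a
spike member that the classifier cannot resolve to species level is
indistinguishable from native members of the same genus, so `tag_spike()`
warns on any member label above species rank. Second, quantification is
scale-free: multiplying all counts in a sample by a constant leaves the
absolute profile unchanged, which the test suite checks as an invariant.

## qPCR anchoring

When classification is too coarse to recognize spike members at all — the
common case for environmental communities — the alternative anchor is the
sample's total 16S copy number from qPCR: $\hat{a}_{is} = p_{is} \, T_s$
with $p_{is}$ the relative abundance and $T_s$ the qPCR total. This requires
columns normalized to 1 (enforced to $10^{-6}$) and gives abundances in 16S
copies rather than cells; no per-taxon 16S copy-number correction is
applied.

## Spike volume design

The standard-addition rule sizes the spike so the DNA of its most abundant
member is a small target fraction $f$ (default 1%) of sample DNA:
$V = f \, D_\text{sample} / (c_\text{spike} \, f_\text{top})$ in µL. Large
enough to survive library preparation, small enough not to consume
sequencing depth.

# Viability

PMA enters membrane-compromised cells and blocks their DNA from sequencing.
Its efficacy for a taxon is the depleted signal fraction

$$ E = 1 - a_\text{post} / a_\text{pre}, $$

computed on **absolute** abundances: treatment shrinks the total, so
relative abundances can rise for taxa that were in fact depleted — the
`depletion_table()` marks exactly those (relative up, absolute down)
alongside a four-way classification (complete depletion / reduced /
unchanged / increased-anomaly) that partitions the taxon set.

One circularity had to be resolved here. An all-dead spike (the commercial
standard's viable fraction is negligible) is itself depleted by PMA, so it
cannot anchor the *treated* sample's absolute abundances. `pair_profiles()`
therefore anchors both sides with qPCR totals, which are measured on the
extracted DNA and are treatment-independent. With that anchor, an all-dead,
fully depleted spike yields $E = 1$ exactly, and a designed half-viable
mixture yields $E = 0.5$ up to multinomial noise — both are acceptance-level
checks. Negative efficacies (post exceeding pre) are reported, not clipped,
with an anomaly flag: they are informative about quantification noise.

Formula provenance: the efficacy definition is pinned down by its two fixed
points — 1 for the fully nonviable ideal and 0.5 for the designed
half-viable mixture — rather than by an external reference, and
$1 - \text{post}/\text{pre}$ is the unique affine statistic with those
values that is invariant to common rescaling of pre and post.

# Profile hygiene and decision rules

* **Singletons** — taxa supported by exactly one read summed over *all*
  samples of a table — are spurious classifier output and are removed.
  Whether the original rule was global or per-sample is not determinable; a
  global sum was chosen because the artifacts in question are
  classifier-level, not sample-level, and the operation is idempotent either
  way.
* **Lowest classifiable rank**: lineages are collapsed to their deepest
  named rank (`s_Pseudomonas fragi`, or `k_Bacteria` for a kingdom-only
  assignment), with `unclassified` for an empty lineage.
* **Filtration rule**: whole-cell filtration costs 13–44% biomass and only
  pays when the nonbacterial fraction is large; the rule recommends it
  strictly above 1% by default, with the domain set and threshold exposed
  as parameters.
* **Library input rule**: DNA input strictly above 11.2 ng is `pass`
  (reliably over $10^5$ raw reads with tagmentation library prep); at or
  below, `low`. Both rules use strict inequalities, matching the
  "more than" phrasing of the underlying observations.

# Sequencing-effort prediction

## Stage 1: metadata to Nd category

Nonpareil diversity (Nd, natural-log bp) summarizes a community's sequence
space; across hospital-environment surveys it is approximately normal, with
90% of samples in [15.4, 20.0]. Because the usable signal in categorical
metadata is coarse, Nd is discretized into ordinal categories of uniform
width (conventionally 2.5, 1.0 or 0.5 Nd units) and a random forest is
trained to predict the category from eight features: location, building,
study, country, touch frequency, sample type, sampling method, sample
pooling.

Binning anchors at the observed minimum with $K =
\lceil \text{span}/\text{width} \rceil$ and an inclusive maximum; explicit
edges can override the anchoring (`make_category_scheme(edges = ...)`),
since externally defined binnings rarely share one anchor. Out-of-range
values error at training time (`strict`) and clamp to end bins at
prediction time (`clamp`).

Features are one-hot encoded with an explicit `"unknown"` level — missing
metadata is a value, not an absence, and prediction-time vocabularies never
silently extend. The forest's `mtry` is tuned by repeated cross-validation
(5 folds × 5 repeats by default) on mean balanced accuracy; every random
choice (split, folds, forests, permutations) derives from one user seed,
and identical seeds give bit-identical reports.

## Evaluation metrics

Per-class balanced accuracy is one-vs-rest $(\text{recall} +
\text{specificity})/2$, averaged over classes present in the truth; Cohen's
kappa comes from the full confusion matrix; AUC is macro-averaged
one-vs-rest on class probabilities. Because the categories discretize a
continuum, most errors land in adjacent bins; the adjacency-tolerant
variant recodes predictions within ±1 category as correct before computing
the metrics, and reduces exactly to the plain metrics at tolerance 0. All
three are cross-checked in the tests against a brute-force oracle that
expands confusion matrices into label vectors and recounts from first
principles, exhaustively over all 2-class matrices with cells ≤ 4 and all
3-class matrices with cells ≤ 2 plus a seeded random sample of 3-class
matrices with cells ≤ 4 (full 3-class exhaustion at cells ≤ 4 is ~1.95
million matrices; the sampled lattice keeps the suite fast without
weakening the 2-class exhaustion).

## Importance and ablation

Feature importance is **permutation importance on held-out folds**: within
each fold a forest is fit on the training part and each feature is permuted
in the held-out part, the score being the drop in balanced accuracy.
Impurity-based importance was rejected because it is not comparable across
one-hot encodings of vocabularies with different sizes. Ablation retrains
under identical settings without a feature subset and reports the retention
ratio of cross-validated balanced accuracy; retention above 95% reads as
"dispensable", which is how the artificial `study` feature — a batch-effect
proxy no future sample possesses — is justified for exclusion at prediction
time.

## Stage 2: Nd to effort

Projected effort to 95% coverage is log-linear in Nd:

$$ \ln(\text{LR}^*) = 1.14 \, \text{Nd} + 1.21
   \qquad (\text{adjusted } R^2 = 0.6012, \; n = 956), $$

fit by OLS with $\text{adj-}R^2 = 1 - (1 - R^2)(n-1)/(n-2)$. Prediction
exponentiates the linear predictor with a $\pm 1.96\,\hat\sigma$ band on
the log scale. A predicted *category* is resolved to its bin midpoint,
which minimizes the worst-case discretization error (width/2); chaining
classifier → midpoint → regression therefore carries a ln-effort error
bounded by $|\text{slope}| \cdot \text{width}/2$ plus the regression band,
a property the tests verify by simulation.

For coverage targets other than 95%, the package interpolates a per-sample
Nonpareil effort/coverage curve: linearly in $(\ln \text{effort},
\text{coverage})$ space, exact at nodes, monotone by construction, ties on
flat segments resolved to the smallest effort, and **never extrapolated**
beyond the last curve point — projection beyond the curve is the upstream
tool's job, not an interpolation's.

# The synthetic-data generator

Every stage is testable without downloads because the generator reproduces
the statistical structure the analysis assumes, with defaults frozen to the
survey conditions:

* **Metadata/Nd table** (`meta_nd_config()`): $n = 956$; Nd mean 17.7 with
  *marginal* sd 1.398, chosen so the central 90% normal interval is exactly
  [15.4, 20.0] (half-width $2.3 = 1.645 \sigma$). The systematic part of
  the signal sits in location effects (±0.18, ±0.54, ±0.90) and building
  effects (±1/6, ±0.5); the residual sd is derived as
  $\sqrt{1.398^2 - \text{Var(effects)}} = 1.199$ so the marginal sd is
  preserved (with zero effects it is 1.398 itself). The mixture's mass in
  [15.4, 20.0] is 0.8999 analytically. Effort follows
  $\ln(\text{LR}^*) = 1.14\,\text{Nd} + 1.21 + \varepsilon$ with
  $\sigma_\varepsilon = 1.298$, which solves
  $R^2 = a^2\sigma^2/(a^2\sigma^2 + \sigma_\varepsilon^2) = 0.6012$. The
  six remaining features are sampled independently of Nd, i.e. they are
  honest noise features for importance recovery.
* **Paired profiles** (`community_config()`): 30 native taxa with power-law
  abundances totalling $10^9$ copies, viable fractions spanning
  [0.05, 0.95], an 8-member all-dead equimolar spike at $10^6$ copies each,
  $10^5$ reads/sample in triplicate. Reads are multinomial (no
  overdispersion by default — no noise model is specified by the source
  material, and multinomial is the minimal assumption); qPCR totals carry
  lognormal noise (strictly positive, median-unbiased, sd configurable, 0 =
  noiseless); a detection limit optionally censors low-count taxa from the
  profile while the truth table retains them.

What the generator does **not** emulate: classifier misassignment between
related taxa, contaminant reads, PMA toxicity to viable cells, overdispersed
(run-to-run) count noise unless the `overdispersion` option is raised, and
real vocabularies' study-confounded sampling designs. Passing
tests on synthetic data therefore demonstrate the pipeline's correctness
and statistical calibration, not robustness to those real-data pathologies.

# Numerical and degenerate-input choices

* Counts must be non-negative integers; profiles with all-singleton taxa
  empty with a warning rather than erroring.
* Efficacy with zero pre-treatment abundance is an error naming the taxon
  (undefined, not 0/0-silent).
* Category edges are compared with a $10^{-9}$ relative slack so exact
  interval multiples do not spawn empty bins.
* Random-forest class predictions break probability ties toward the lower
  ordinal label for determinism.
* The effort regression refuses constant Nd, nonpositive LRstar, and
  $n < 3$.
* Coverage conversion tolerates $10^{-9}$ relative fuzz at curve endpoints
  so exp/log round trips stay in range.

# Problem sizes in the shipped analyses

The numbered scripts under `analysis/` and the test suite use the survey
scale ($n = 956$) for all distribution and regression work, 20 replicate
surveys for estimator-recovery summaries, triplicate $10^5$-read samples
for quantification and viability, and reduced cross-validation designs
(3–5 folds, 1–2 repeats, 200–500 trees) where a full 5×5 design would add
runtime without changing what the check demonstrates; the full 5×5 default
remains the training default.

# Known limitations

* Spike members sharing a collapsed label with native taxa are inseparable;
  the loader warns but cannot correct.
* Per-taxon 16S copy-number variation is not corrected; qPCR-anchored
  abundances are in copy units.
* The classifier is flat, not hierarchical; with 11 categories the exact
  accuracy is modest and the ±1-category metric is the honest summary.
* The effort model is a population-level regression; per-sample curves,
  when available, dominate it for targets below 95%.
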