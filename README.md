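# metasurv

Quantitative, viability-aware metagenomic surveillance of built
environments.

Hospital surfaces, sink drains and similar built-environment reservoirs
harbor pathogens, and untargeted metagenomic sequencing is the natural
surveillance instrument — but it struggles on exactly these samples: they
are low-biomass, read counts are compositional rather than quantitative,
sequencing cannot tell viable cells from dead DNA, and the sequencing
effort a sample needs is unknown until after it has been sequenced.
`metasurv` is an R package plus a set of analysis drivers for the
computational side of a surveillance workflow that addresses all four
problems. It is aimed at microbiome researchers and infection-prevention
teams who already have taxonomic profiles (SSU-classifier count tables),
qPCR totals and Nonpareil summaries, and need the downstream quantification,
viability and planning analyses to be reproducible and tested.

## What it computes

**Absolute abundance.** With a multi-species spike-in internal standard of
known per-member input *q_m* and observed reads *r_ms*, each sample gets a
copies-per-read factor `c_s = median_m(q_m / r_ms)` and native taxa are
estimated as `a_is = r_is * c_s`. When classification is too coarse to
recognize spike members, relative abundances are anchored by the 16S qPCR
total instead: `a_is = p_is * T_s`.

**PMA viability efficacy.** For paired samples with and without propidium
monoazide treatment, a taxon's efficacy is `E = 1 - post/pre` on absolute
abundances (1 = fully depleted, the ideal for an all-dead spike; 0.5 for a
designed half-viable standard). Paired profiles are anchored with qPCR
totals because an all-dead spike is itself depleted by treatment and cannot
anchor the treated side.

**Sequencing-effort prediction.** A two-stage model: (1) a random forest
predicts a sample's Nonpareil diversity (Nd) category from eight accessible
metadata features (location, building, study, country, touch frequency,
sample type, sampling method, sample pooling), evaluated with balanced
accuracy, Cohen's kappa, macro AUC and an adjacency-tolerant (±1 category)
balanced accuracy; (2) the required effort to 95% coverage follows
`ln(LRstar) = 1.14 * Nd + 1.21` (adjusted R² = 0.6012 on the 956-sample
hospital-environment survey the model emulates). Other coverage targets are
reached by monotone interpolation of per-sample Nonpareil effort/coverage
curves.

**Decision support.** Whole-cell filtration is recommended only when the
nonbacterial read fraction exceeds 1% (strict); library DNA input above
11.2 ng is flagged `pass` (reliably > 1e5 raw reads); singleton taxa
(one read across the whole table) are removed as classifier artifacts;
lineages collapse to their lowest classifiable rank.

A synthetic-data module generates survey tables and paired spiked profiles
with exactly the statistical structure above, so every stage is testable
end-to-end without any download.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on generated
data; `Rscript analysis/01_simulate_survey.R` through `05_effort_model.R`.
A condensed session:

```r
library(metasurv)

# paired spiked profiles, triplicate, 1e5 reads, all-dead 8-member spike
sim <- simulate_profiles(community_config(qpcr_sd = 0, seed = 1))
spike <- default_spike_spec()

factors <- spike_scaling_factors(sim$profile_pre, spike)
factors$copies_per_read
#> [1] 10417.8 10417.8 10056.6             # ~1e4 copies/read

paired <- pair_profiles(sim$profile_pre, sim$profile_post,
                        sim$qpcr_pre, sim$qpcr_post)
head(spike_efficacy_table(paired, spike)[, c("taxon", "efficacy")], 3)
#>                      taxon efficacy
#> 1 s_Pseudomonas aeruginosa        1
#> 2       s_Escherichia coli        1
#> 3    s_Salmonella enterica        1   # ideal: all-dead spike fully depleted

# the 956-sample survey emulation and the two-stage depth model
survey <- simulate_metadata_nd(meta_nd_config(seed = 20260930))
mean(survey$nd >= 15.4 & survey$nd <= 20.0)
#> [1] 0.8943515                          # ~90% in the reference band

em <- fit_effort_model(survey$nd, survey$lrstar)
em
#> <effort_model> ln(LRstar) = 1.084 * Nd + 2.226  (adj R2 = 0.6005, n = 956)

predict_lrstar(em, nd = 17.7)$effort
#> [1] 1989006574                         # ~2.0 Gbp for a typical sample
```

Interpretation: the spike factors convert reads to 16S copies (so a taxon
with 500 reads is ~5e6 copies per sample); efficacy 1 means PMA removed the
nonviable spike completely; and a sample at the survey's median diversity
needs roughly 2 Gbp to reach 95% abundance-weighted average coverage, with
the driver scripts showing the ±1-category accuracy gain and the
feature-ablation result (dropping `study` retains ~100% of accuracy;
location + building alone retain ~99%).

## Layout

```
R/                      package code (profiles, quantify, viability,
                        metrics, depth model, coverage, simulators)
analysis/01..05_*.R     narrative drivers writing tables under results/
tests/testthat/         unit, property and acceptance tests
scripts/acceptance.R    headline-quantity recomputation (JSON out)
vignettes/              methods vignette (models, parameters, design)
```
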