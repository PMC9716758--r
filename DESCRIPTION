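Package: metasurv
Title: Quantitative, Viability-Aware Metagenomic Surveillance of Built Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for metagenomics-based environmental surveillance of
    low-biomass built environments such as hospital surfaces. Converts
    taxonomic read-count profiles to absolute abundances using multi-species
    spike-in internal standards or 16S rRNA gene qPCR totals, quantifies the
    efficacy of propidium monoazide (PMA) viability treatment in paired
    treated/untreated samples, and predicts the sequencing effort required to
    reach a target abundance-weighted average coverage from accessible sample
    metadata via a two-stage model: an ordinal random-forest classifier of
    Nonpareil diversity categories followed by a log-linear effort regression.
    Includes decision-support rules for low-biomass sample processing
    (whole-cell filtration, library DNA input), coverage-curve conversion
    between sequencing effort and coverage targets, and a synthetic-data
    generator reproducing the statistical structure of hospital-environment
    metagenome surveys for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    fitdistrplus,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
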