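#!/usr/bin/env Rscript
# Generate the synthetic inputs every later stage consumes:
#  - a 956-sample hospital-environment survey table (8 metadata features,
#    Nonpareil diversity Nd, projected effort LRstar at 95% coverage);
#  - triplicate paired spiked profiles with and without PMA treatment,
#    plus qPCR 16S totals and the generating truth.
# Everything is reproducible from the seed below.

library(metasurv)

seed <- 20260930
dir.create("results", showWarnings = FALSE)

survey <- simulate_metadata_nd(meta_nd_config(seed = seed))
write.csv(survey, "results/survey_metadata_nd.csv", row.names = FALSE)
cat(sprintf("survey: %d samples; Nd mean %.2f sd %.3f; %.1f%% in [15.4, 20.0]\n",
            nrow(survey), mean(survey$nd), sd(survey$nd),
            100 * mean(survey$nd >= 15.4 & survey$nd <= 20.0)))

cfg <- community_config(qpcr_sd = 0.05, seed = seed)
sim <- simulate_profiles(cfg)
write_profile(sim$profile_pre, "results/profile_no_pma.tsv")
write_profile(sim$profile_post, "results/profile_pma.tsv")
write.csv(sim$qpcr_pre, "results/qpcr_no_pma.csv", row.names = FALSE)
write.csv(sim$qpcr_post, "results/qpcr_pma.csv", row.names = FALSE)
write.csv(sim$truth, "results/community_truth.csv", row.names = FALSE)
cat(sprintf("profiles: %d taxa (8 spike members) x %d paired samples at %d reads\n",
            nrow(sim$profile_pre$counts), ncol(sim$profile_pre$counts),
            cfg$reads_per_sample))
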