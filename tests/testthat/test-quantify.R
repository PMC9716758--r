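make_spiked_profile <- function(spike_reads, native_reads = c(s_X = 500L),
                                sample = "s1") {
  taxa <- c(names(native_reads), names(spike_reads))
  counts <- matrix(c(native_reads, spike_reads), ncol = 1,
                   dimnames = list(taxa, sample))
  profile_matrix(counts, lineages = vector("list", length(taxa)),
                 domain_tag = c(rep("bacteria", length(native_reads)),
                                rep("spike", length(spike_reads))))
}

test_that("per-member factors and median aggregation match hand arithmetic", {
  spec <- spike_spec(c("s_A", "s_B", "s_C"), 1e6)
  prof <- make_spiked_profile(c(s_A = 1000L, s_B = 900L, s_C = 1100L))
  sf <- spike_scaling_factors(prof, spec)
  pm <- attr(sf, "per_member")
  expect_equal(sort(unname(pm[, "s1"])), sort(c(1000, 1e6 / 900, 1e6 / 1100)),
               tolerance = 1e-12)
  expect_equal(sf$copies_per_read, 1000)       # median of {909.1, 1000, 1111.1}
  # single-member median is the member factor itself
  sf1 <- spike_scaling_factors(make_spiked_profile(c(s_A = 1000L)),
                               spike_spec("s_A", 1e6))
  expect_equal(sf1$copies_per_read, 1000)
  # mean aggregation as the alternative
  sfm <- spike_scaling_factors(prof, spec, aggregate = "mean")
  expect_equal(sfm$copies_per_read, mean(c(1000, 1e6 / 900, 1e6 / 1100)))
})

test_that("missing or zero-read spike members raise named errors", {
  spec <- spike_spec(c("s_A", "s_B"), 1e6)
  expect_error(spike_scaling_factors(make_spiked_profile(c(s_A = 100L)), spec),
               "s_B")
  prof0 <- make_spiked_profile(c(s_A = 100L, s_B = 0L))
  expect_error(spike_scaling_factors(prof0, spec), "s_B in s1")
})

test_that("spike-anchored absolute abundance scales reads and drops the spike", {
  spec <- spike_spec("s_A", 1e6)
  prof <- make_spiked_profile(c(s_A = 1000L),
                              native_reads = c(s_X = 500L, s_Y = 0L))
  sf <- spike_scaling_factors(prof, spec)
  abs_prof <- absolute_from_spike(prof, sf, spec)
  expect_equal(abs_prof["s_X", "s1"], 5e5)
  expect_equal(abs_prof["s_Y", "s1"], 0)
  expect_false("s_A" %in% rownames(abs_prof))
  # proportionality: normalizing the output reproduces non-spike relative abundances
  rel_out <- abs_prof[, 1] / sum(abs_prof[, 1])
  rel_in <- c(500, 0) / 500
  expect_equal(unname(rel_out), rel_in / sum(rel_in))
})

test_that("spike quantification is invariant to common count rescaling", {
  spec <- spike_spec(c("s_A", "s_B"), c(2e6, 1e6))
  prof <- make_spiked_profile(c(s_A = 800L, s_B = 400L),
                              native_reads = c(s_X = 600L))
  k <- 7L
  prof_k <- prof
  prof_k$counts <- prof$counts * k
  a1 <- absolute_from_spike(prof, spike_scaling_factors(prof, spec), spec)
  a2 <- absolute_from_spike(prof_k, spike_scaling_factors(prof_k, spec), spec)
  expect_equal(a1, a2)
})

test_that("median factor tolerates one aberrant spike member better than the mean", {
  spec <- spike_spec(paste0("s_", LETTERS[1:5]), 1e6)
  reads <- c(s_A = 1000L, s_B = 1050L, s_C = 950L, s_D = 1000L, s_E = 1020L)
  prof <- make_spiked_profile(reads)
  base_med <- spike_scaling_factors(prof, spec)$copies_per_read
  base_mean <- spike_scaling_factors(prof, spec, "mean")$copies_per_read
  reads_bad <- reads; reads_bad["s_C"] <- reads_bad["s_C"] * 10L
  prof_bad <- make_spiked_profile(reads_bad)
  med_shift <- abs(spike_scaling_factors(prof_bad, spec)$copies_per_read - base_med)
  mean_shift <- abs(spike_scaling_factors(prof_bad, spec, "mean")$copies_per_read -
                    base_mean)
  # the median moves only between neighboring order statistics
  pm <- sort(attr(spike_scaling_factors(prof, spec), "per_member")[, 1])
  expect_lte(med_shift, diff(range(pm)))
  expect_lt(med_shift, mean_shift)
})

test_that("qPCR-anchored absolute abundance scales normalized columns", {
  rel <- matrix(c(0.2, 0.8), 2, 1, dimnames = list(c("X", "Y"), "s1"))
  qp <- data.frame(sample_id = "s1", copies_per_sample = 1e7)
  expect_equal(unname(absolute_from_qpcr(rel, qp)[, 1]), c(2e6, 8e6))
  qp0 <- data.frame(sample_id = "s1", copies_per_sample = 0)
  expect_warning(z <- absolute_from_qpcr(rel, qp0), "zero")
  expect_equal(unname(z[, 1]), c(0, 0))
  bad <- matrix(c(0.2, 0.7), 2, 1, dimnames = list(c("X", "Y"), "s1"))
  expect_error(absolute_from_qpcr(bad, qp), "sum to 1")
})

test_that("spike volume design follows the 1%-of-top-species rule and is linear", {
  expect_equal(design_spike_volume(100, 10, 0.2), 0.5)
  expect_equal(design_spike_volume(200, 10, 0.2), 1.0)
  expect_error(design_spike_volume(100, 10, 0.2, target_fraction = 0), "range")
  expect_error(design_spike_volume(-1, 10, 0.2), "range")
})

test_that("spike specs read from CSV and YAML, warning on shallow members", {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(taxon = c("s_A", "s_B"), input_quantity = 1e6,
                              designed_viable_fraction = c(0, 0.5)),
                   csv, row.names = FALSE)
  sp <- read_spike_spec(csv)
  expect_s3_class(sp, "spike_spec")
  expect_equal(sp$designed_viable_fraction, c(0, 0.5))

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("members:",
               "  - taxon: s_A",
               "    input_quantity: 1.0e6",
               "  - taxon: g_OnlyGenus",
               "    input_quantity: 2.0e6",
               "    designed_viable_fraction: 0.5",
               "total_dna_conc: 10"), yml)
  sp2 <- read_spike_spec(yml)
  expect_equal(sp2$input_quantity, c(1e6, 2e6))
  expect_equal(attr(sp2, "total_dna_conc"), 10)

  prof <- make_spiked_profile(c(s_A = 10L, g_OnlyGenus = 10L))
  expect_warning(tag_spike(prof, sp2), "g_OnlyGenus")
})

test_that("simulated communities are re-quantified within multinomial error", {
  cfg <- community_config(reads_per_sample = 1e5, n_samples = 1,
                          qpcr_sd = 0, seed = 42)
  sim <- simulate_profiles(cfg)
  sf <- spike_scaling_factors(sim$profile_pre, cfg$spike)
  est <- absolute_from_spike(sim$profile_pre, sf, cfg$spike)
  truth <- sim$truth[!sim$truth$is_spike, ]
  reads <- sim$profile_pre$counts[truth$taxon, 1]
  keep <- reads >= 50
  rel_err <- abs(est[truth$taxon, 1] - truth$abundance) / truth$abundance
  expect_lt(median(rel_err[keep]), 0.10)
})
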