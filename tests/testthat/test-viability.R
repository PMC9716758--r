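test_that("PMA efficacy matches the ideal, designed, and null cases", {
  expect_equal(as.numeric(pma_efficacy(100, 0)), 1.0)
  expect_equal(as.numeric(pma_efficacy(100, 50)), 0.5)
  expect_equal(as.numeric(pma_efficacy(100, 100)), 0.0)
  expect_error(pma_efficacy(c(s_A = 0), c(s_A = 10)), "s_A")
  # post > pre is reported negative and flagged, not clipped
  eff <- pma_efficacy(100, 120)
  expect_equal(as.numeric(eff), -0.2)
  expect_true(attr(eff, "anomaly"))
})

test_that("efficacy is invariant to common rescaling of pre and post", {
  pre <- c(a = 120, b = 35, c = 900)
  post <- c(a = 10, b = 35, c = 0)
  for (k in c(0.5, 3, 1e6)) {
    expect_equal(as.numeric(pma_efficacy(pre * k, post * k)),
                 as.numeric(pma_efficacy(pre, post)))
  }
})

test_that("depletion classes partition the taxon set and mark rel-up/abs-down", {
  paired <- structure(list(
    sample_id = "s1",
    abs_pre  = c(t1 = 10, t2 = 100, t3 = 50, t4 = 20),
    abs_post = c(t1 = 0,  t2 = 60,  t3 = 50, t4 = 25),
    rel_pre  = c(t1 = 10, t2 = 100, t3 = 50, t4 = 20) / 180,
    rel_post = c(t1 = 0,  t2 = 60,  t3 = 50, t4 = 25) / 135),
    class = "paired_sample")
  dt <- depletion_table(paired)
  expect_identical(dt$class,
                   c("complete_depletion", "reduced", "unchanged",
                     "increased_flag"))
  expect_identical(sum(table(dt$class)), nrow(dt))  # one class per taxon
  # t3: abs unchanged but rel rose (denominator shrank) -> not marked (abs not down)
  expect_false(dt$rel_up_abs_down[3])
  # a reduced taxon whose share rose is marked
  paired$abs_post <- c(t1 = 0, t2 = 90, t3 = 20, t4 = 25)
  paired$rel_post <- paired$abs_post / sum(paired$abs_post)
  dt2 <- depletion_table(paired)
  expect_true(dt2$rel_up_abs_down[dt2$taxon == "t2"])
  # all unchanged
  paired$abs_post <- paired$abs_pre
  paired$rel_post <- paired$rel_pre
  expect_true(all(depletion_table(paired)$class == "unchanged"))
})

test_that("cultivation cross-reference is exact set algebra", {
  res <- cultivation_crossref(c("a", "b", "c"), c("b", "c", "d"), c("b"))
  expect_setequal(res$both, c("b", "c"))
  expect_identical(res$seq_only, "a")
  expect_identical(res$culture_only, "d")
  expect_identical(res$pma_retained, "b")
  expect_equal(unname(res$counts[c("n_seq", "n_culture")]), c(3L, 3L))
  empty <- cultivation_crossref(c("a"), character(0))
  expect_length(empty$both, 0)
  expect_length(empty$culture_only, 0)
})

test_that("the study's detected-taxa counts reproduce from its taxon lists", {
  # 12 cultivated and 11 sequence-detected taxa, overlapping on 3 confirmed
  culture <- c("s_Pseudomonas fragi", "s_Pseudomonas stutzeri",
               "s_Pseudomonas fluorescens", paste0("s_Culture only ", 1:9))
  seqd <- c("s_Pseudomonas fragi", "s_Pseudomonas stutzeri",
            "s_Pseudomonas fluorescens", paste0("s_Seq only ", 1:8))
  res <- cultivation_crossref(seqd, culture)
  expect_equal(unname(res$counts["n_culture"]), 12L)
  expect_equal(unname(res$counts["n_seq"]), 11L)
  expect_equal(unname(res$counts["both"]), 3L)
})

test_that("paired simulated samples recover per-taxon viable fractions", {
  cfg <- community_config(reads_per_sample = 2e5, n_samples = 3,
                          qpcr_sd = 0, seed = 7)
  sim <- simulate_profiles(cfg)
  paired <- pair_profiles(sim$profile_pre, sim$profile_post,
                          sim$qpcr_pre, sim$qpcr_post)
  p <- paired[[1]]
  truth <- sim$truth[!sim$truth$is_spike, ]
  reads <- sim$profile_pre$counts[truth$taxon, 1]
  keep <- reads >= 200
  est <- as.numeric(pma_efficacy(p$abs_pre[truth$taxon[keep]],
                                 p$abs_post[truth$taxon[keep]]))
  expect_lt(max(abs(est - (1 - truth$viable_fraction[keep]))), 0.12)
})

test_that("spike efficacy table hits the designed efficacy across replicates", {
  # all-dead spike, ideal depletion -> efficacy exactly 1
  cfg0 <- community_config(qpcr_sd = 0, seed = 5)
  sim0 <- simulate_profiles(cfg0)
  et0 <- spike_efficacy_table(
    pair_profiles(sim0$profile_pre, sim0$profile_post,
                  sim0$qpcr_pre, sim0$qpcr_post), cfg0$spike)
  expect_equal(et0$efficacy, rep(1, 8))
  expect_equal(et0$designed_efficacy, rep(1, 8))
  expect_false(any(et0$anomaly))
  # designed half-viable spike -> efficacy 0.5 within multinomial error
  cfg5 <- community_config(spike = default_spike_spec(
                             input_quantity = 5e6,
                             designed_viable_fraction = 0.5),
                           reads_per_sample = 2e5, qpcr_sd = 0, seed = 6)
  sim5 <- simulate_profiles(cfg5)
  et5 <- spike_efficacy_table(
    pair_profiles(sim5$profile_pre, sim5$profile_post,
                  sim5$qpcr_pre, sim5$qpcr_post), cfg5$spike)
  expect_equal(et5$efficacy, rep(0.5, 8), tolerance = 0.08)
  expect_equal(et5$designed_efficacy, rep(0.5, 8))
  # no depletion at all -> efficacy 0 for every member
  pp <- pair_profiles(sim0$profile_pre, sim0$profile_pre,
                      sim0$qpcr_pre, sim0$qpcr_pre)
  et_same <- spike_efficacy_table(pp, cfg0$spike)
  expect_equal(et_same$efficacy, rep(0, 8))
})
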