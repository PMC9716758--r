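#!/usr/bin/env Rscript
# Stage 2: the log-linear effort model and end-to-end prediction.
#  - OLS of ln(LRstar) on Nd over the survey;
#  - effort predictions for reference Nd values and category midpoints;
#  - coverage-curve conversion to targets other than 95%.

library(metasurv)

survey <- read.csv("results/survey_metadata_nd.csv")

em <- fit_effort_model(survey$nd, survey$lrstar)
print(em)
write.csv(data.frame(slope = em$slope, intercept = em$intercept,
                     adj_r2 = em$adj_r2, residual_sd = em$residual_sd,
                     n = em$n),
          "results/effort_model.csv", row.names = FALSE)

pred <- predict_lrstar(em, nd = c(16, 17.7, 19))
pred$gbp <- pred$effort / 1e9
print(format(pred, digits = 3))
write.csv(pred, "results/effort_predictions.csv", row.names = FALSE)

# end-to-end: metadata -> category -> midpoint Nd -> effort
scheme <- make_category_scheme(survey$nd, interval = 1.0)
sp <- split_train_test(survey, seed = 99)
clf <- train_depth_classifier(sp$train, scheme, seed = 99, folds = 5,
                              repeats = 2, num_trees = 300)
new_sample <- data.frame(location = "sink", building = "bldg_A",
                         country = "USA", touch_frequency = "high",
                         sample_type = "sink", sampling_method = "swab",
                         sample_pooling = "not_pooled")  # no "study" known
res <- predict_from_metadata(new_sample, clf, em)
cat(sprintf(
  "new sink sample -> category %d (Nd %.2f-%.2f), effort at 95%%: %.2e bp [%.1e, %.1e]\n",
  res$category, res$nd_range[1], res$nd_range[2],
  res$effort_95, res$lower, res$upper))

# lower targets via a Nonpareil effort/coverage curve
curve <- coverage_curve(c(1e7, 1e8, 5e8, 2e9), c(0.55, 0.80, 0.92, 0.97))
for (target in c(0.8, 0.9)) {
  res_t <- predict_from_metadata(new_sample, clf, em,
                                 target_coverage = target, curve = curve)
  cat(sprintf("  effort at %.0f%% coverage (sample curve): %.2e bp\n",
              100 * target, res_t$effort_target))
}
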