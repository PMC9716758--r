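test_that("distribution fitting identifies the generating family by AIC", {
  set.seed(101)
  fit_n <- fit_nd_distribution(stats::rnorm(5000, 17.7, 1.4))
  expect_identical(fit_n$best_family, "norm")
  expect_equal(unname(fit_n$fits$norm$estimate["mean"]), 17.7, tolerance = 0.05)
  expect_equal(fit_n$kurtosis, 3, tolerance = 0.3)
  set.seed(102)
  fit_l <- fit_nd_distribution(stats::rlogis(5000, 17.7, 1))
  expect_identical(fit_l$best_family, "logis")
  expect_error(fit_nd_distribution(rep(17, 100)), "constant")
})

test_that("category schemes bin by span/width with an inclusive maximum", {
  nd <- c(15.0, 16.2, 17.9, 19.999)
  s1 <- make_category_scheme(nd, interval = 1.0)
  expect_identical(s1$K, 5L)
  s2 <- make_category_scheme(nd, interval = 2.5)
  expect_identical(s2$K, 2L)
  expect_identical(categorize(min(nd), s1), 1L)
  expect_identical(categorize(max(nd), s1), s1$K)
  # exact multiples of the interval do not spawn an empty extra bin
  s3 <- make_category_scheme(c(15, 20), interval = 1.0)
  expect_identical(s3$K, 5L)
  expect_identical(categorize(20, s3), 5L)
  expect_error(make_category_scheme(nd, interval = 0), "range")
  expect_error(categorize(14.0, s1, mode = "strict"), "outside")
  expect_warning(lab <- categorize(14.0, s1, mode = "clamp"), "clamp")
  expect_identical(lab, 1L)
  # explicit-edge override
  so <- make_category_scheme(edges = seq(14.75, 20.25, by = 0.5))
  expect_identical(so$K, 11L)
  expect_error(make_category_scheme(edges = c(1, 2, 4)), "uniform")
  # midpoints are the mean of neighboring edges
  expect_equal(category_midpoints(s3), seq(15.5, 19.5, by = 1))
})

test_that("train/test split is a disjoint 4:1 partition, reproducible by seed", {
  tab <- data.frame(i = 1:100)
  sp <- split_train_test(tab, seed = 11)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  expect_length(intersect(sp$train$i, sp$test$i), 0)
  expect_setequal(c(sp$train$i, sp$test$i), 1:100)
  sp2 <- split_train_test(tab, seed = 11)
  expect_identical(sp$train$i, sp2$train$i)
  diff_seeds <- vapply(1:10, function(s)
    !identical(split_train_test(tab, seed = s)$train$i, sp$train$i), TRUE)
  expect_true(mean(diff_seeds) > 0.8)
  expect_error(split_train_test(tab[1:4, , drop = FALSE]), "5 rows")
})

make_separable_table <- function(n = 120, seed = 1) {
  set.seed(seed)
  vocab <- default_metadata_vocabulary()
  loc <- sample(c("sink", "floor", "bedrail"), n, replace = TRUE)
  nd_by_loc <- c(sink = 15.5, floor = 16.5, bedrail = 17.5)
  df <- data.frame(location = loc, stringsAsFactors = FALSE)
  for (f in setdiff(names(vocab), "location"))
    df[[f]] <- sample(vocab[[f]], n, replace = TRUE)
  df$nd <- unname(nd_by_loc[loc])
  df
}

test_that("a deterministic location->category map is learned perfectly", {
  tab <- make_separable_table()
  scheme <- make_category_scheme(edges = c(15, 16, 17, 18))
  sp <- split_train_test(tab, seed = 3)
  clf <- train_depth_classifier(sp$train, scheme, folds = 3, repeats = 2,
                                seed = 5, num_trees = 200)
  pred <- predict(clf, sp$test)
  truth <- categorize(sp$test$nd, scheme)
  expect_equal(confusion_metrics(truth, pred$category, 3)$accuracy, 1)
  # determinism: identical seeds give identical predictions and CV scores
  clf2 <- train_depth_classifier(sp$train, scheme, folds = 3, repeats = 2,
                                 seed = 5, num_trees = 200)
  expect_identical(predict(clf2, sp$test)$category, pred$category)
  expect_identical(clf2$cv_scores, clf$cv_scores)
})

test_that("uninformative features score near chance and training guards classes", {
  set.seed(21)
  vocab <- default_metadata_vocabulary()
  n <- 160
  tab <- data.frame(location = sample(vocab$location, n, TRUE),
                    building = sample(vocab$building, n, TRUE),
                    stringsAsFactors = FALSE)
  tab$nd <- sample(c(15.5, 16.5), n, TRUE)          # independent of features
  scheme <- make_category_scheme(edges = c(15, 16, 17))
  sp <- split_train_test(tab, seed = 2)
  clf <- train_depth_classifier(sp$train, scheme,
                                features = c("location", "building"),
                                folds = 3, repeats = 2, seed = 2,
                                num_trees = 200)
  truth <- categorize(sp$test$nd, scheme)
  ba <- confusion_metrics(truth, predict(clf, sp$test)$category,
                          2)$mean_balanced_accuracy
  expect_lt(abs(ba - 0.5), 0.2)
  # a class entirely absent from training is an error
  tab1 <- tab; tab1$nd <- rep(15.5, n)
  expect_error(train_depth_classifier(tab1, scheme, folds = 3, repeats = 1,
                                      features = c("location", "building")),
               "absent")
})

test_that("permutation importance recovers the informative feature first", {
  cfg <- meta_nd_config(n = 400, seed = 31)
  tab <- simulate_metadata_nd(cfg)
  scheme <- make_category_scheme(tab$nd, interval = 2.5)
  clf <- train_depth_classifier(tab, scheme, folds = 3, repeats = 1,
                                seed = 31, num_trees = 200,
                                mtry_grid = 6)
  imp <- variable_importance(clf, folds = 3, n_perm = 2)
  expect_setequal(imp$feature, metasurv:::METADATA_FEATURES)
  expect_true("location" %in% imp$feature[1:2])
  # reproducible ranking under the same seed
  clf_b <- train_depth_classifier(tab, scheme, folds = 3, repeats = 1,
                                  seed = 31, num_trees = 200, mtry_grid = 6)
  expect_identical(variable_importance(clf_b, folds = 3, n_perm = 2), imp)
})

test_that("ablating noise features retains accuracy; ablating signal destroys it", {
  cfg <- meta_nd_config(n = 400, seed = 17)
  tab <- simulate_metadata_nd(cfg)
  scheme <- make_category_scheme(tab$nd, interval = 2.5)
  ab_noise <- feature_ablation(tab, scheme, drop = "sample_pooling",
                               seed = 17, folds = 3, repeats = 1,
                               num_trees = 200, mtry_grid = 6)
  expect_gt(ab_noise$retention, 0.9)
  ab_sig <- feature_ablation(tab, scheme,
                             drop = c("location", "building"),
                             seed = 17, folds = 3, repeats = 1,
                             num_trees = 200, mtry_grid = 6)
  expect_lt(ab_sig$accuracy_without, ab_sig$accuracy_with)
  expect_error(feature_ablation(tab, scheme,
                                drop = metasurv:::METADATA_FEATURES),
               "every feature")
})

test_that("the effort model recovers noiseless coefficients and refuses bad input", {
  nd <- seq(14, 21, length.out = 40)
  lrstar <- exp(1.14 * nd + 1.21)
  em <- fit_effort_model(nd, lrstar)
  expect_equal(em$slope, 1.14, tolerance = 1e-10)
  expect_equal(em$intercept, 1.21, tolerance = 1e-8)
  expect_equal(em$r2, 1, tolerance = 1e-10)
  expect_error(fit_effort_model(rep(17, 10), rep(1e8, 10)), "constant")
  expect_error(fit_effort_model(nd, -lrstar), "> 0")
})

test_that("effort prediction exponentiates the linear model and is monotone", {
  em <- structure(list(slope = 1.14, intercept = 1.21, residual_sd = 0.5,
                       adj_r2 = NA, r2 = NA, n = NA, p_value = NA, fit = NULL),
                  class = "effort_model")
  p16 <- predict_lrstar(em, nd = 16)
  expect_equal(log(p16$effort), 19.45)
  expect_equal(p16$effort, exp(19.45))      # ~2.80e8 bp
  expect_equal(p16$lower, exp(19.45 - 1.96 * 0.5))
  nds <- seq(14, 21, by = 0.5)
  expect_true(all(diff(predict_lrstar(em, nd = nds)$effort) > 0))
  scheme <- make_category_scheme(edges = c(15, 16, 17))
  pc <- predict_lrstar(em, category = 2, scheme = scheme)
  expect_equal(pc$nd, 16.5)
})

test_that("metadata-to-effort chaining stays within the discretization bound", {
  tab <- make_separable_table(n = 150, seed = 8)
  scheme <- make_category_scheme(edges = c(15, 16, 17, 18))
  clf <- train_depth_classifier(tab, scheme, folds = 3, repeats = 1,
                                seed = 8, num_trees = 200, mtry_grid = 6)
  em <- fit_effort_model(tab$nd, exp(1.14 * tab$nd + 1.21))
  new <- data.frame(location = "floor", stringsAsFactors = FALSE)
  res <- predict_from_metadata(new, clf, em)
  expect_identical(res$category, 2L)
  expect_equal(res$nd_range, c(16, 17))
  # ln-effort error bounded by slope * interval/2 plus the regression band
  true_ln <- 1.14 * 16.5 + 1.21
  expect_lt(abs(log(res$effort_95) - true_ln),
            abs(em$slope) * scheme$interval / 2 + 1.96 * em$residual_sd + 0.05)
  # non-default coverage target requires a curve and uses it
  curve <- coverage_curve(c(1e6, 1e8, 1e9), c(0.3, 0.95, 0.99))
  res2 <- predict_from_metadata(new, clf, em, target_coverage = 0.99,
                                curve = curve)
  expect_equal(res2$effort_target, 1e9)
  expect_error(predict_from_metadata(new, clf, em, target_coverage = 0.5),
               "curve")
})
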