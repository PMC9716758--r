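# Two-stage sequencing-effort prediction:
#   stage 1 — classify Nonpareil diversity (Nd) categories from accessible
#             sample metadata with a random forest;
#   stage 2 — convert Nd to required effort via the log-linear model
#             ln(LRstar) = slope * Nd + intercept.

#' Fit candidate distributions to Nonpareil diversity values
#'
#' Maximum-likelihood fits (normal and logistic by default) compared by AIC,
#' plus the (skewness^2, kurtosis) moment coordinates used by Cullen-Frey
#' style diagnostics of distribution shape.
#'
#' @param nd Numeric vector of Nd values (natural-log bp), `n >= 10`,
#'   nonconstant.
#' @param families Distribution names understood by
#'   [fitdistrplus::fitdist()]; default `c("norm", "logis")`.
#' @return List with `best_family` (lowest AIC), `fits` (per family:
#'   `estimate`, `loglik`, `aic`), `aic` (named vector), `skewness`,
#'   `skewness_sq`, `kurtosis` (moment kurtosis, normal = 3).
#' @export
fit_nd_distribution <- function(nd, families = c("norm", "logis")) {
  stopifnot(is.numeric(nd))
  nd <- nd[is.finite(nd)]
  if (length(nd) < 10L) stop_bad("need at least 10 finite Nd values")
  if (stats::sd(nd) == 0) stop_bad("Nd values are constant; nothing to fit")
  fits <- lapply(families, function(f) {
    fit <- fitdistrplus::fitdist(nd, f)
    list(estimate = fit$estimate, loglik = fit$loglik, aic = fit$aic)
  })
  names(fits) <- families
  aic <- vapply(fits, `[[`, 0, "aic")
  m <- mean(nd)
  s2 <- mean((nd - m)^2)
  skew <- mean((nd - m)^3) / s2^1.5
  kurt <- mean((nd - m)^4) / s2^2
  list(best_family = families[which.min(aic)], fits = fits, aic = aic,
       skewness = skew, skewness_sq = skew^2, kurtosis = kurt)
}

#' Build an ordinal category scheme over Nd
#'
#' Converts the continuous response into K ordinal categories of uniform
#' width. Default anchoring places the first edge at `min(nd)` with
#' `K = ceiling((max - min)/interval)` bins; the maximum is inclusive in the
#' last bin. Explicit `edges` override the anchoring (uniform, strictly
#' increasing) for reproducing externally defined binnings.
#'
#' @param nd Training Nd values (nonconstant) used to anchor the edges;
#'   ignored when `edges` is supplied.
#' @param interval Bin width in Nd units, `> 0` (conventional choices 2.5,
#'   1.0, 0.5).
#' @param edges Optional explicit edge vector (length K + 1).
#' @return A `category_scheme`: list with `interval`, `edges`, `K`, `labels`.
#' @export
make_category_scheme <- function(nd = NULL, interval = NULL, edges = NULL) {
  if (is.null(edges)) {
    assert_scalar_num(interval, "interval", 0, strict_lower = TRUE)
    stopifnot(is.numeric(nd), length(nd) >= 2L)
    nd <- nd[is.finite(nd)]
    lo <- min(nd); hi <- max(nd)
    if (hi == lo) stop_bad("Nd values are constant; cannot build bins")
    K <- ceiling((hi - lo) / interval - 1e-9)
    edges <- lo + interval * (0:K)
  } else {
    stopifnot(is.numeric(edges), length(edges) >= 2L)
    widths <- diff(edges)
    if (any(widths <= 0)) stop_bad("edges must be strictly increasing")
    if (diff(range(widths)) > 1e-8 * mean(widths))
      stop_bad("edges must be uniformly spaced")
    interval <- widths[1]
    K <- length(edges) - 1L
  }
  structure(list(interval = interval, edges = edges, K = as.integer(K),
                 labels = seq_len(K)),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme> K =", x$K, "bins of width", x$interval,
      "over [", x$edges[1], ",", x$edges[length(x$edges)], "]\n")
  invisible(x)
}

#' Map Nd values to ordinal category labels
#'
#' @param nd Numeric Nd values.
#' @param scheme A [make_category_scheme()] result.
#' @param mode `"strict"` errors on values outside the edge range (training
#'   time); `"clamp"` maps them to the nearest end bin with a warning
#'   (prediction time).
#' @return Integer labels in `1..K`; the upper edge is inclusive in bin K.
#' @export
categorize <- function(nd, scheme, mode = c("strict", "clamp")) {
  stopifnot(inherits(scheme, "category_scheme"), is.numeric(nd))
  mode <- match.arg(mode)
  lo <- scheme$edges[1]; hi <- scheme$edges[length(scheme$edges)]
  out_of_range <- nd < lo | nd > hi
  if (any(out_of_range)) {
    if (mode == "strict")
      stop_bad("Nd value(s) outside the scheme range [", lo, ", ", hi, "]: ",
               paste(utils::head(nd[out_of_range], 5), collapse = ", "))
    warning("clamping ", sum(out_of_range),
            " Nd value(s) outside the scheme range to end bins", call. = FALSE)
  }
  lab <- findInterval(nd, scheme$edges, rightmost.closed = TRUE)
  pmin(pmax(lab, 1L), scheme$K)
}

#' Midpoint Nd of each category
#'
#' The representative Nd of a predicted category is its bin midpoint, which
#' minimizes the worst-case discretization error `interval / 2`.
#'
#' @param scheme A [make_category_scheme()] result.
#' @return Numeric vector of K midpoints.
#' @export
category_midpoints <- function(scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  (scheme$edges[-1] + scheme$edges[-length(scheme$edges)]) / 2
}

#' Random train/test split
#'
#' @param table Data frame with `n >= 5` rows.
#' @param ratio Training fraction, default `0.8` (the 4:1 split).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with `train` and `test` data frames (disjoint, union = input,
#'   `nrow(train) = round(ratio * n)`).
#' @export
split_train_test <- function(table, ratio = 0.8, seed = 1) {
  stopifnot(is.data.frame(table))
  n <- nrow(table)
  if (n < 5L) stop_bad("need at least 5 rows to split")
  assert_scalar_num(ratio, "ratio", 0, 1, strict_lower = TRUE,
                    strict_upper = TRUE)
  set.seed(seed)
  idx <- sample.int(n, round(ratio * n))
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

# --- categorical one-hot encoding with an explicit "unknown" level ----------

build_feature_spec <- function(data, features) {
  miss <- setdiff(features, names(data))
  if (length(miss))
    stop_bad("feature column(s) missing from data: ", paste(miss, collapse = ", "))
  levs <- lapply(features, function(f)
    sort(unique(c(as.character(data[[f]]), "unknown"))))
  stats::setNames(levs, features)
}

encode_features <- function(data, feature_spec) {
  cols <- lapply(names(feature_spec), function(f) {
    levs <- feature_spec[[f]]
    v <- if (f %in% names(data)) as.character(data[[f]])
         else rep("unknown", nrow(data))
    v[is.na(v) | !(v %in% levs)] <- "unknown"
    m <- matrix(0, nrow(data), length(levs),
                dimnames = list(NULL, paste(f, levs, sep = ".")))
    m[cbind(seq_along(v), match(v, levs))] <- 1
    m
  })
  do.call(cbind, cols)
}

rf_fit <- function(X, y, mtry, num_trees, seed) {
  ranger::ranger(x = as.data.frame(X), y = y, mtry = mtry,
                 num.trees = num_trees, probability = TRUE,
                 seed = seed, num.threads = 1)
}

rf_predict <- function(fit, X, K) {
  pr <- stats::predict(fit, data = as.data.frame(X),
                       num.threads = 1)$predictions
  prob <- matrix(0, nrow(X), K)
  colnames(prob) <- as.character(seq_len(K))
  prob[, colnames(pr)] <- pr
  pred <- max.col(prob, ties.method = "first")
  list(pred = pred, prob = prob)
}

make_folds <- function(n, folds, repeats, seed) {
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    f <- sample(rep_len(seq_len(folds), n))
    lapply(seq_len(folds), function(k) which(f == k))
  })
}

cv_balanced_accuracy <- function(X, y, K, folds, repeats, mtry, num_trees, seed) {
  plan <- make_folds(length(y), folds, repeats, seed)
  seeds <- derive_seeds(seed, folds * repeats)
  i <- 0L
  scores <- unlist(lapply(plan, function(rep_folds) {
    vapply(rep_folds, function(test_idx) {
      i <<- i + 1L
      fit <- rf_fit(X[-test_idx, , drop = FALSE], y[-test_idx],
                    mtry, num_trees, seeds[i])
      pr <- rf_predict(fit, X[test_idx, , drop = FALSE], K)
      confusion_metrics(as.integer(as.character(y[test_idx])), pr$pred,
                        K)$mean_balanced_accuracy
    }, 0)
  }))
  mean(scores)
}

#' Train the metadata-to-Nd-category random-forest classifier
#'
#' Stage 1 of the effort-prediction pipeline. Categorical features are
#' one-hot encoded with an explicit `"unknown"` level; `mtry` is tuned by
#' repeated cross-validation (5 folds, 5 repeats by default) on mean balanced
#' accuracy, and the final forest is refit on the full training set. All
#' randomness (folds, forests) flows from `seed`.
#'
#' @param train Data frame holding the feature columns and an `nd` column.
#' @param scheme A [make_category_scheme()]; training labels are
#'   `categorize(train$nd, scheme, "strict")`. Every class must appear in the
#'   training data (error) and should have at least `folds` members
#'   (warning).
#' @param features Feature column names; default the eight metadata features.
#' @param folds,repeats Cross-validation design, default 5 x 5.
#' @param seed Integer seed.
#' @param num_trees Trees per forest, default 500.
#' @param mtry_grid Candidate `mtry` values; default
#'   `sqrt(p)`, `p/4`, `p/2` over the one-hot width p.
#' @param categorize_mode `"strict"` (default) errors on Nd outside the
#'   scheme range; `"clamp"` maps such samples to the end bins, for override
#'   schemes narrower than the observed range.
#' @return A `depth_classifier` object.
#' @export
train_depth_classifier <- function(train, scheme, features = METADATA_FEATURES,
                                   folds = 5, repeats = 5, seed = 1,
                                   num_trees = 500, mtry_grid = NULL,
                                   categorize_mode = c("strict", "clamp")) {
  stopifnot(is.data.frame(train), inherits(scheme, "category_scheme"))
  if (!"nd" %in% names(train)) stop_bad("`train` needs an `nd` column")
  categorize_mode <- match.arg(categorize_mode)
  labels <- suppressWarnings(categorize(train$nd, scheme,
                                        mode = categorize_mode))
  present <- sort(unique(labels))
  if (!all(scheme$labels %in% present))
    stop_bad("class(es) absent from training data: ",
             paste(setdiff(scheme$labels, present), collapse = ", "))
  small <- table(labels) < folds
  if (any(small))
    warning("class(es) with fewer members than CV folds: ",
            paste(names(which(small)), collapse = ", "), call. = FALSE)
  feature_spec <- build_feature_spec(train, features)
  X <- encode_features(train, feature_spec)
  y <- factor(labels, levels = scheme$labels)
  p <- ncol(X)
  if (is.null(mtry_grid))
    mtry_grid <- sort(unique(pmax(1, c(floor(sqrt(p)), floor(p / 4),
                                       floor(p / 2)))))
  seeds <- derive_seeds(seed, length(mtry_grid) + 1L)
  cv <- vapply(seq_along(mtry_grid), function(i)
    cv_balanced_accuracy(X, y, scheme$K, folds, repeats, mtry_grid[i],
                         num_trees, seeds[i]), 0)
  best <- mtry_grid[which.max(cv)]
  model <- rf_fit(X, y, best, num_trees, seeds[length(seeds)])
  structure(list(scheme = scheme, feature_spec = feature_spec,
                 features = names(feature_spec), model = model, mtry = best,
                 cv_scores = stats::setNames(cv, mtry_grid),
                 cv_config = list(folds = folds, repeats = repeats),
                 num_trees = num_trees, seed = seed,
                 categorize_mode = categorize_mode,
                 train_data = train[c(features, "nd")]),
            class = "depth_classifier")
}

#' @export
print.depth_classifier <- function(x, ...) {
  cat("<depth_classifier> random forest,", x$scheme$K, "ordinal classes,",
      length(x$features), "features (mtry =", x$mtry, ")\n")
  cat("CV mean balanced accuracy:",
      sprintf("%.3f", max(x$cv_scores)), "\n")
  invisible(x)
}

#' Predict Nd categories for new samples
#'
#' @param object A [train_depth_classifier()] result.
#' @param newdata Data frame with the classifier's feature columns; missing
#'   columns or unseen levels are encoded as `"unknown"`.
#' @param ... Unused.
#' @return List with integer `category` labels and the `prob` matrix.
#' @export
predict.depth_classifier <- function(object, newdata, ...) {
  X <- encode_features(newdata, object$feature_spec)
  rf <- rf_predict(object$model, X, object$scheme$K)
  list(category = rf$pred, prob = rf$prob)
}

#' Permutation importance of metadata features on held-out folds
#'
#' Model-agnostic importance: within each cross-validation fold a forest is
#' fit on the fold's training part, and each feature column is permuted (in
#' raw categorical space, before encoding) in the held-out part; the score is
#' the mean drop in balanced accuracy. Ranking is descending with
#' alphabetical tie-break; fully deterministic given the classifier's seed.
#'
#' @param classifier A [train_depth_classifier()] result.
#' @param folds Folds for the importance pass (default the classifier's CV
#'   fold count).
#' @param n_perm Permutations per feature and fold, default 3.
#' @return Data frame `feature`, `importance` (mean balanced-accuracy drop),
#'   `sd`, ordered by rank.
#' @export
variable_importance <- function(classifier, folds = NULL, n_perm = 3) {
  stopifnot(inherits(classifier, "depth_classifier"))
  data <- classifier$train_data
  scheme <- classifier$scheme
  features <- classifier$features
  if (is.null(folds)) folds <- classifier$cv_config$folds
  labels <- suppressWarnings(categorize(data$nd, scheme,
                                        mode = classifier$categorize_mode))
  y <- factor(labels, levels = scheme$labels)
  seed <- derive_seeds(classifier$seed, 2)[2]
  plan <- make_folds(nrow(data), folds, 1L, seed)[[1]]
  seeds <- derive_seeds(seed, folds)
  drops <- matrix(NA_real_, folds, length(features),
                  dimnames = list(NULL, features))
  for (k in seq_len(folds)) {
    test_idx <- plan[[k]]
    Xtr <- encode_features(data[-test_idx, , drop = FALSE],
                           classifier$feature_spec)
    fit <- rf_fit(Xtr, y[-test_idx], classifier$mtry, classifier$num_trees,
                  seeds[k])
    test <- data[test_idx, , drop = FALSE]
    base <- confusion_metrics(
      as.integer(as.character(y[test_idx])),
      rf_predict(fit, encode_features(test, classifier$feature_spec),
                 scheme$K)$pred, scheme$K)$mean_balanced_accuracy
    set.seed(seeds[k])
    for (f in features) {
      perm_scores <- vapply(seq_len(n_perm), function(j) {
        shuf <- test
        shuf[[f]] <- sample(shuf[[f]])
        confusion_metrics(
          as.integer(as.character(y[test_idx])),
          rf_predict(fit, encode_features(shuf, classifier$feature_spec),
                     scheme$K)$pred, scheme$K)$mean_balanced_accuracy
      }, 0)
      drops[k, f] <- base - mean(perm_scores)
    }
  }
  imp <- colMeans(drops)
  sds <- apply(drops, 2, stats::sd)
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             sd = unname(sds[ord]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Performance retention after dropping features
#'
#' Trains two classifiers under identical settings — with the full feature
#' set and with `drop` excluded — and reports the retention ratio of
#' cross-validated mean balanced accuracy (`without / with`). Retention above
#' 0.95 is conventionally read as "the dropped features were dispensable".
#'
#' @param table Data frame with feature columns and `nd`.
#' @param scheme A [make_category_scheme()].
#' @param drop Character vector of features to exclude (proper subset).
#' @param features Full feature set, default the eight metadata features.
#' @param seed Integer seed shared by both fits.
#' @param ... Passed to [train_depth_classifier()] (e.g. `folds`, `repeats`,
#'   `num_trees`).
#' @return List with `retention`, `accuracy_with`, `accuracy_without`,
#'   `kept`, `dropped`.
#' @export
feature_ablation <- function(table, scheme, drop,
                             features = METADATA_FEATURES, seed = 1, ...) {
  stopifnot(all(drop %in% features))
  kept <- setdiff(features, drop)
  if (!length(kept)) stop_bad("cannot drop every feature")
  full <- train_depth_classifier(table, scheme, features = features,
                                 seed = seed, ...)
  red <- train_depth_classifier(table, scheme, features = kept,
                                seed = seed, ...)
  acc_with <- max(full$cv_scores)
  acc_without <- max(red$cv_scores)
  list(retention = acc_without / acc_with,
       accuracy_with = acc_with, accuracy_without = acc_without,
       kept = kept, dropped = drop)
}

#' Fit the log-linear sequencing-effort model
#'
#' Stage 2: ordinary least squares of `ln(lrstar)` on Nd. On the
#' hospital-environment survey this relationship is
#' `ln(LRstar) = 1.14 * Nd + 1.21` with adjusted R-squared 0.6012.
#'
#' @param nd Nd values (nonconstant, `n >= 3`).
#' @param lrstar Projected efforts at 95% coverage, in bp, all `> 0`.
#' @return An `effort_model`: list with `slope`, `intercept`, `adj_r2`, `r2`,
#'   `n`, `residual_sd`, `p_value`, and the underlying `lm` fit.
#' @export
fit_effort_model <- function(nd, lrstar) {
  stopifnot(is.numeric(nd), is.numeric(lrstar), length(nd) == length(lrstar))
  ok <- is.finite(nd) & is.finite(lrstar)
  nd <- nd[ok]; lrstar <- lrstar[ok]
  if (length(nd) < 3L) stop_bad("need at least 3 observations")
  if (any(lrstar <= 0)) stop_bad("lrstar must be > 0")
  if (stats::var(nd) == 0) stop_bad("Nd is constant; slope is unidentifiable")
  fit <- stats::lm(log(lrstar) ~ nd)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 n = length(nd), residual_sd = sm$sigma,
                 p_value = unname(sm$coefficients[2, 4]),
                 fit = fit),
            class = "effort_model")
}

#' @export
print.effort_model <- function(x, ...) {
  cat(sprintf("<effort_model> ln(LRstar) = %.3f * Nd + %.3f  (adj R2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$adj_r2, x$n))
  invisible(x)
}

#' Predict required sequencing effort from Nd
#'
#' `effort = exp(slope * nd + intercept)` with a `+/- 1.96 * residual_sd`
#' prediction band on the log scale; strictly increasing in Nd. A category
#' label plus its scheme may be given instead of Nd, in which case the bin
#' midpoint is used.
#'
#' @param model A fitted [fit_effort_model()].
#' @param nd Nd value(s); omit when `category` is given.
#' @param category Optional ordinal label(s) with `scheme` to resolve the
#'   midpoint Nd.
#' @param scheme Required with `category`.
#' @return Data frame `nd`, `effort` (bp), `lower`, `upper`.
#' @export
predict_lrstar <- function(model, nd = NULL, category = NULL, scheme = NULL) {
  stopifnot(inherits(model, "effort_model"))
  if (is.null(nd)) {
    if (is.null(category) || is.null(scheme))
      stop_bad("supply `nd`, or `category` together with `scheme`")
    nd <- category_midpoints(scheme)[as.integer(category)]
  }
  ln_eff <- model$slope * nd + model$intercept
  half <- 1.96 * model$residual_sd
  data.frame(nd = nd, effort = exp(ln_eff),
             lower = exp(ln_eff - half), upper = exp(ln_eff + half))
}

#' End-to-end effort prediction from sample metadata
#'
#' Chains the two stages: classify the sample's Nd category from metadata,
#' resolve the category to its midpoint Nd, and convert to sequencing effort
#' at 95% coverage. For a different coverage target, a per-sample Nonpareil
#' effort/coverage curve must be supplied and the conversion defers to
#' [effort_at_coverage()].
#'
#' @param features One-row data frame (or list) of metadata feature values;
#'   features the classifier was trained on but absent here are encoded
#'   `"unknown"`.
#' @param classifier A [train_depth_classifier()] result.
#' @param effort_model A [fit_effort_model()] result.
#' @param target_coverage Coverage target, default `0.95`.
#' @param curve Optional [coverage_curve()] used when
#'   `target_coverage != 0.95`.
#' @return List with `category`, `nd_range` (bin edges), `nd_mid`,
#'   `effort_95` (bp, with `lower`/`upper`), `target_coverage`,
#'   `effort_target`.
#' @export
predict_from_metadata <- function(features, classifier, effort_model,
                                  target_coverage = 0.95, curve = NULL) {
  stopifnot(inherits(classifier, "depth_classifier"),
            inherits(effort_model, "effort_model"))
  assert_scalar_num(target_coverage, "target_coverage", 0, 1,
                    strict_lower = TRUE)
  if (!is.data.frame(features)) features <- as.data.frame(features,
                                                          stringsAsFactors = FALSE)
  pr <- stats::predict(classifier, features)
  k <- pr$category[1]
  scheme <- classifier$scheme
  nd_mid <- category_midpoints(scheme)[k]
  eff <- predict_lrstar(effort_model, nd = nd_mid)
  effort_target <- if (abs(target_coverage - 0.95) < 1e-12) eff$effort else {
    if (is.null(curve))
      stop_bad("a coverage curve is required for targets other than 0.95")
    effort_at_coverage(curve, target_coverage)
  }
  list(category = k,
       nd_range = c(scheme$edges[k], scheme$edges[k + 1]),
       nd_mid = nd_mid,
       effort_95 = eff$effort, lower = eff$lower, upper = eff$upper,
       target_coverage = target_coverage, effort_target = effort_target,
       prob = pr$prob)
}
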