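# Synthetic-data generators reproducing the statistical structure of
# hospital-environment metagenome surveys: a metadata/Nd/LRstar table for the
# depth model, and paired spiked PMA/no-PMA count profiles for the
# quantification and viability stages.

#' Configuration for the metadata/Nd/effort simulator
#'
#' Defaults emulate the hospital-related environmental survey conditions:
#' `n = 956` samples; Nd approximately normal with mean 17.7 and *marginal*
#' standard deviation 1.398, so that 90% of values fall in `[15.4, 20.0]`
#' (half-width `2.3 = 1.645 * 1.398`); effort linked by
#' `ln(LRstar) = 1.14 * Nd + 1.21` with residual sd 1.298, which solves
#' `R^2 = slope^2 * sd_nd^2 / (slope^2 * sd_nd^2 + effort_sd^2) = 0.6012`.
#' Location and building carry the systematic part of the Nd signal through
#' per-level effects; the residual sd is derived so the marginal sd stays at
#' `nd_sd` (with zero effects the residual is `nd_sd` itself). The remaining
#' six features are sampled independently of Nd.
#'
#' @param n Number of samples.
#' @param mu Baseline (grand mean) Nd, natural-log bp.
#' @param nd_sd Target marginal standard deviation of Nd.
#' @param slope,intercept Effort model coefficients on the ln scale.
#' @param effort_sd Residual sd of `ln(LRstar)` around the linear model.
#' @param location_effects,building_effects Named or unnamed per-level Nd
#'   effects (must average to 0 under the level weights); lengths must match
#'   the vocabulary levels.
#' @param vocabulary Feature level sets, default
#'   [default_metadata_vocabulary()].
#' @param weights Optional named list of per-feature sampling weights
#'   (uniform when omitted); each must sum to 1.
#' @param seed Integer seed.
#' @return A `meta_nd_config` list; `$residual_sd` holds the derived
#'   within-group sd.
#' @export
meta_nd_config <- function(n = 956, mu = 17.7, nd_sd = 1.398,
                           slope = 1.14, intercept = 1.21, effort_sd = 1.298,
                           location_effects = c(-0.90, -0.54, -0.18,
                                                0.18, 0.54, 0.90),
                           building_effects = c(-0.50, -1 / 6, 1 / 6, 0.50),
                           vocabulary = default_metadata_vocabulary(),
                           weights = NULL, seed = 1) {
  stopifnot(n >= 1)
  assert_scalar_num(nd_sd, "nd_sd", 0, strict_lower = TRUE)
  assert_scalar_num(effort_sd, "effort_sd", 0, strict_lower = TRUE)
  if (length(location_effects) != length(vocabulary$location))
    stop_bad("location_effects must match the location vocabulary length")
  if (length(building_effects) != length(vocabulary$building))
    stop_bad("building_effects must match the building vocabulary length")
  w <- lapply(METADATA_FEATURES, function(f) {
    levs <- vocabulary[[f]]
    wf <- if (!is.null(weights[[f]])) weights[[f]]
          else rep(1 / length(levs), length(levs))
    if (length(wf) != length(levs)) stop_bad("weights for `", f,
                                             "` must match its levels")
    if (abs(sum(wf) - 1) > 1e-8) stop_bad("weights for `", f,
                                          "` must sum to 1")
    wf
  })
  names(w) <- METADATA_FEATURES
  mloc <- sum(w$location * location_effects)
  mbld <- sum(w$building * building_effects)
  if (abs(mloc) > 1e-8 || abs(mbld) > 1e-8)
    stop_bad("per-level effects must average to 0 under the level weights")
  v_eff <- sum(w$location * location_effects^2) +
           sum(w$building * building_effects^2)
  if (v_eff >= nd_sd^2)
    stop_bad("effect variance (", round(v_eff, 4),
             ") exceeds the marginal Nd variance; shrink the effects")
  structure(list(n = as.integer(n), mu = mu, nd_sd = nd_sd,
                 residual_sd = sqrt(nd_sd^2 - v_eff),
                 slope = slope, intercept = intercept, effort_sd = effort_sd,
                 location_effects = location_effects,
                 building_effects = building_effects,
                 vocabulary = vocabulary, weights = w,
                 seed = as.integer(seed)),
            class = "meta_nd_config")
}

#' Simulate a metadata/Nd/LRstar sample table
#'
#' Draws the eight categorical features from their vocabularies, composes
#' `nd = mu + effect(location) + effect(building) + N(0, residual_sd)` and
#' `lrstar = exp(slope * nd + intercept + N(0, effort_sd))`. Fully
#' reproducible from the config seed.
#'
#' @param config A [meta_nd_config()].
#' @return Data frame with `sample_id`, the eight feature columns, `nd`, and
#'   `lrstar` (bp).
#' @export
simulate_metadata_nd <- function(config = meta_nd_config()) {
  stopifnot(inherits(config, "meta_nd_config"))
  set.seed(config$seed)
  n <- config$n
  feats <- lapply(METADATA_FEATURES, function(f)
    sample(config$vocabulary[[f]], n, replace = TRUE,
           prob = config$weights[[f]]))
  names(feats) <- METADATA_FEATURES
  loc_eff <- config$location_effects[match(feats$location,
                                           config$vocabulary$location)]
  bld_eff <- config$building_effects[match(feats$building,
                                           config$vocabulary$building)]
  nd <- config$mu + loc_eff + bld_eff + stats::rnorm(n, 0, config$residual_sd)
  lrstar <- exp(config$slope * nd + config$intercept +
                stats::rnorm(n, 0, config$effort_sd))
  cbind(data.frame(sample_id = sprintf("sample_%04d", seq_len(n)),
                   stringsAsFactors = FALSE),
        as.data.frame(feats, stringsAsFactors = FALSE),
        data.frame(nd = nd, lrstar = lrstar))
}

#' Default multi-species spike-in specification
#'
#' An 8-member all-bacterial internal standard modeled on a commercial mock
#' community, equimolar at `1e6` copies per member and fully nonviable by
#' design (`designed_viable_fraction = 0`).
#'
#' @param input_quantity Copies per member, default `1e6`.
#' @param designed_viable_fraction Viable fraction per member, default 0.
#' @return A [spike_spec()].
#' @export
default_spike_spec <- function(input_quantity = 1e6,
                               designed_viable_fraction = 0) {
  members <- c("s_Pseudomonas aeruginosa", "s_Escherichia coli",
               "s_Salmonella enterica", "s_Lactobacillus fermentum",
               "s_Enterococcus faecalis", "s_Staphylococcus aureus",
               "s_Listeria monocytogenes", "s_Bacillus subtilis")
  spike_spec(members, input_quantity, designed_viable_fraction)
}

#' Configuration for the paired-profile community simulator
#'
#' Defaults describe a low-biomass surface community: 30 native bacterial
#' taxa with power-law absolute abundances totalling `1e9` 16S copies,
#' per-taxon viable fractions spanning `[0.05, 0.95]`, the
#' [default_spike_spec()] internal standard, `1e5` reads per sample and
#' triplicate paired samples.
#'
#' @param taxa Native taxon labels.
#' @param abundances True absolute abundances (copies) per native taxon.
#' @param viable_fractions Per-taxon viable fractions in `[0, 1]`.
#' @param spike A [spike_spec()].
#' @param reads_per_sample Sequencing depth per sample (reads).
#' @param n_samples Number of paired pre/post samples.
#' @param qpcr_sd Lognormal sd of qPCR totals around the true copy sum
#'   (0 = noiseless).
#' @param detection_limit Minimum read count for a taxon to appear in the
#'   profile (counts below it are censored to 0).
#' @param overdispersion Dirichlet-multinomial overdispersion: 0 (default)
#'   gives plain multinomial reads; larger values perturb each sample's
#'   composition with Dirichlet concentration `sum(pool)/overdispersion`
#'   scaled weights, for robustness experiments.
#' @param seed Integer seed.
#' @return A `community_config` list.
#' @export
community_config <- function(taxa = NULL, abundances = NULL,
                             viable_fractions = NULL,
                             spike = default_spike_spec(),
                             reads_per_sample = 1e5, n_samples = 3,
                             qpcr_sd = 0.1, detection_limit = 0,
                             overdispersion = 0, seed = 1) {
  if (is.null(taxa)) taxa <- sprintf("s_Native taxon %02d", 1:30)
  nt <- length(taxa)
  if (is.null(abundances)) {
    p <- (1:nt)^-1.5
    abundances <- 1e9 * p / sum(p)
  }
  if (is.null(viable_fractions))
    viable_fractions <- seq(0.05, 0.95, length.out = nt)
  stopifnot(length(abundances) == nt, length(viable_fractions) == nt,
            inherits(spike, "spike_spec"))
  if (any(abundances < 0)) stop_bad("abundances must be >= 0")
  if (any(viable_fractions < 0 | viable_fractions > 1))
    stop_bad("viable fractions must be in [0, 1]")
  if (any(taxa %in% spike$taxon))
    stop_bad("native taxa and spike members must not share labels")
  assert_scalar_num(reads_per_sample, "reads_per_sample", 0,
                    strict_lower = TRUE)
  assert_scalar_num(qpcr_sd, "qpcr_sd", 0)
  assert_scalar_num(overdispersion, "overdispersion", 0)
  structure(list(taxa = taxa, abundances = abundances,
                 viable_fractions = viable_fractions, spike = spike,
                 reads_per_sample = as.integer(reads_per_sample),
                 n_samples = as.integer(n_samples),
                 qpcr_sd = qpcr_sd, detection_limit = detection_limit,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "community_config")
}

#' Simulate paired spiked PMA/no-PMA profiles with qPCR totals
#'
#' Pre-treatment reads are multinomial over native absolute abundances plus
#' spike inputs; post-treatment reads are multinomial over
#' `abundance * viable_fraction` (spike members scaled by their designed
#' viable fraction — PMA ideally depletes exactly the nonviable part). qPCR
#' totals are the true copy sums under lognormal noise. The retained truth
#' table enables parameter-recovery tests.
#'
#' @param config A [community_config()].
#' @return List with [profile_matrix()] objects `profile_pre` and
#'   `profile_post`, data frames `qpcr_pre` and `qpcr_post`, and `truth`
#'   (taxon, abundance, viable_fraction, is_spike).
#' @export
simulate_profiles <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  spike <- config$spike
  taxa <- c(config$taxa, spike$taxon)
  pool_pre <- c(config$abundances, spike$input_quantity)
  pool_post <- c(config$abundances * config$viable_fractions,
                 spike$input_quantity * spike$designed_viable_fraction)
  if (sum(pool_pre) <= 0) stop_bad("total pre-treatment abundance is 0")
  if (sum(pool_post) <= 0) stop_bad("total post-treatment abundance is 0")
  ids <- sprintf("sample_%d", seq_len(config$n_samples))
  od <- if (is.null(config$overdispersion)) 0 else config$overdispersion
  draw <- function(pool) {
    p <- pool / sum(pool)
    m <- if (od > 0) {
      # Dirichlet-multinomial: per-sample composition jitter around p
      vapply(seq_len(config$n_samples), function(s) {
        g <- stats::rgamma(length(p), shape = p / od)
        g[pool == 0] <- 0
        stats::rmultinom(1, config$reads_per_sample, g / sum(g))[, 1]
      }, integer(length(p)))
    } else {
      stats::rmultinom(config$n_samples, config$reads_per_sample, p)
    }
    dimnames(m) <- list(taxa, ids)
    if (config$detection_limit > 0) m[m < config$detection_limit] <- 0
    m
  }
  counts_pre <- draw(pool_pre)
  counts_post <- draw(pool_post)
  noise <- function() if (config$qpcr_sd > 0)
    stats::rlnorm(config$n_samples, 0, config$qpcr_sd) else rep(1, config$n_samples)
  qpcr_pre <- data.frame(sample_id = ids,
                         copies_per_sample = sum(pool_pre) * noise(),
                         stringsAsFactors = FALSE)
  qpcr_post <- data.frame(sample_id = ids,
                          copies_per_sample = sum(pool_post) * noise(),
                          stringsAsFactors = FALSE)
  tags <- c(rep("bacteria", length(config$taxa)),
            rep("spike", nrow(spike)))
  list(
    profile_pre = profile_matrix(counts_pre, lineages = vector("list",
                                                               length(taxa)),
                                 domain_tag = tags),
    profile_post = profile_matrix(counts_post, lineages = vector("list",
                                                                 length(taxa)),
                                  domain_tag = tags),
    qpcr_pre = qpcr_pre, qpcr_post = qpcr_post,
    truth = data.frame(
      taxon = taxa,
      abundance = pool_pre,
      viable_fraction = c(config$viable_fractions,
                          spike$designed_viable_fraction),
      is_spike = c(rep(FALSE, length(config$taxa)), rep(TRUE, nrow(spike))),
      stringsAsFactors = FALSE))
}
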