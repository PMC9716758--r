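# PMA viability-treatment efficacy and per-taxon depletion profiling.

#' PMA treatment efficacy
#'
#' Efficacy of propidium monoazide treatment for a taxon is the fraction of
#' its signal depleted: `1 - post/pre`, computed on absolute abundances
#' (relative abundances distort the comparison because treatment shrinks the
#' denominator). For a fully nonviable population the ideal is 1; for a
#' designed half-viable mixture, 0.5. Values below 0 (post exceeding pre, a
#' quantification anomaly) are returned, not clipped, and flagged via the
#' `anomaly` attribute.
#'
#' @param pre Absolute abundance without PMA; must be `> 0` (vectorized,
#'   optionally named by taxon).
#' @param post Absolute abundance with PMA.
#' @return Numeric vector of efficacies `<= 1`, with logical attribute
#'   `anomaly` marking entries where `post > pre`.
#' @export
pma_efficacy <- function(pre, post) {
  stopifnot(is.numeric(pre), is.numeric(post), length(pre) == length(post))
  zero <- pre <= 0
  if (any(zero)) {
    who <- if (!is.null(names(pre))) paste(names(pre)[zero], collapse = ", ")
           else paste(which(zero), collapse = ", ")
    stop_bad("efficacy undefined for taxa with pre-treatment abundance 0: ", who)
  }
  eff <- 1 - post / pre
  structure(eff, anomaly = post > pre)
}

#' Pair untreated/treated profiles into per-sample comparisons
#'
#' Builds, per sample id, the pre/post absolute and relative abundance
#' vectors over the union taxon set (absent = 0), anchoring absolute
#' abundances with qPCR 16S totals via [absolute_from_qpcr()] — a
#' PMA-independent anchor, since an all-dead spike is itself depleted by
#' treatment and cannot anchor the treated sample.
#'
#' @param profile_pre,profile_post [profile_matrix()] objects sharing sample
#'   ids (no-PMA and PMA respectively).
#' @param qpcr_pre,qpcr_post qPCR tables (`sample_id,copies_per_sample`) for
#'   the corresponding aliquots.
#' @return Named list of `paired_sample` objects, each with elements
#'   `sample_id`, `abs_pre`, `abs_post`, `rel_pre`, `rel_post`.
#' @export
pair_profiles <- function(profile_pre, profile_post, qpcr_pre, qpcr_post) {
  stopifnot(inherits(profile_pre, "profile_matrix"),
            inherits(profile_post, "profile_matrix"))
  ids <- intersect(colnames(profile_pre$counts), colnames(profile_post$counts))
  if (!length(ids)) stop_bad("no shared sample ids between pre and post profiles")
  taxa <- union(rownames(profile_pre$counts), rownames(profile_post$counts))
  align <- function(counts) {
    m <- matrix(0, length(taxa), ncol(counts),
                dimnames = list(taxa, colnames(counts)))
    m[rownames(counts), ] <- counts
    m
  }
  rel_pre <- relative_abundance(align(profile_pre$counts))
  rel_post <- relative_abundance(align(profile_post$counts))
  abs_pre <- absolute_from_qpcr(rel_pre[, ids, drop = FALSE], qpcr_pre)
  abs_post <- absolute_from_qpcr(rel_post[, ids, drop = FALSE], qpcr_post)
  out <- lapply(ids, function(s) {
    structure(list(sample_id = s,
                   abs_pre = abs_pre[, s], abs_post = abs_post[, s],
                   rel_pre = rel_pre[, s], rel_post = rel_post[, s]),
              class = "paired_sample")
  })
  stats::setNames(out, ids)
}

#' Efficacy table for spike-in members across paired replicates
#'
#' Computes [pma_efficacy()] for every spike member in every paired
#' replicate and summarizes each member as mean +/- standard error, alongside
#' its designed efficacy `1 - designed_viable_fraction`.
#'
#' @param paired A `paired_sample` or list of them (see [pair_profiles()]).
#' @param spec A [spike_spec()].
#' @return Data frame with one row per member: `taxon`, `efficacy` (mean over
#'   replicates), `se`, `designed_efficacy`, `n`, `anomaly` (any replicate
#'   with post > pre); per-replicate values in attribute `replicates`.
#' @export
spike_efficacy_table <- function(paired, spec) {
  stopifnot(inherits(spec, "spike_spec"))
  if (inherits(paired, "paired_sample")) paired <- list(paired)
  per_rep <- vapply(paired, function(p) {
    miss <- setdiff(spec$taxon, names(p$abs_pre))
    if (length(miss))
      stop_bad("spike member(s) absent from paired sample ", p$sample_id,
               ": ", paste(miss, collapse = ", "))
    as.numeric(pma_efficacy(p$abs_pre[spec$taxon], p$abs_post[spec$taxon]))
  }, numeric(nrow(spec)))
  per_rep <- matrix(per_rep, nrow = nrow(spec),
                    dimnames = list(spec$taxon, names(paired)))
  n <- ncol(per_rep)
  out <- data.frame(
    taxon = spec$taxon,
    efficacy = rowMeans(per_rep),
    se = apply(per_rep, 1, function(x) {
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    }),
    designed_efficacy = 1 - spec$designed_viable_fraction,
    n = n,
    anomaly = apply(per_rep, 1, function(x) any(x < 0)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, replicates = per_rep)
}

#' Per-taxon abundance change under PMA treatment
#'
#' Classifies every taxon of a paired sample by its absolute-abundance
#' change: `complete_depletion` (pre > 0, post = 0), `reduced` (post < pre),
#' `unchanged`, or `increased_flag` (post > pre, an anomaly). Additionally
#' marks taxa whose relative abundance rose while absolute abundance fell —
#' the distortion that makes relative profiles misleading for viability.
#'
#' @param paired A `paired_sample` (see [pair_profiles()]).
#' @return Data frame with columns `taxon`, `abs_pre`, `abs_post`,
#'   `abs_change`, `rel_change`, `class`, `rel_up_abs_down`.
#' @export
depletion_table <- function(paired) {
  stopifnot(inherits(paired, "paired_sample"))
  pre <- paired$abs_pre; post <- paired$abs_post
  cls <- ifelse(pre > 0 & post == 0, "complete_depletion",
         ifelse(post < pre, "reduced",
         ifelse(post > pre, "increased_flag", "unchanged")))
  abs_change <- post - pre
  rel_change <- paired$rel_post - paired$rel_pre
  data.frame(
    taxon = names(pre),
    abs_pre = as.numeric(pre), abs_post = as.numeric(post),
    abs_change = as.numeric(abs_change),
    rel_change = as.numeric(rel_change),
    class = as.character(cls),
    rel_up_abs_down = as.numeric(rel_change) > 0 & as.numeric(abs_change) < 0,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-reference sequencing, cultivation and PMA-retained taxa
#'
#' Set algebra over collapsed taxon labels: which taxa both methods detect,
#' which only sequencing or only cultivation sees, and which of the detected
#' taxa remain after PMA treatment (viable signal).
#'
#' @param seq_taxa,culture_taxa,pma_taxa Character vectors of labels in the
#'   [collapse_to_lowest_rank()] convention.
#' @return List with elements `both`, `seq_only`, `culture_only`,
#'   `pma_retained` and a named integer vector `counts` (including
#'   `n_seq` and `n_culture`).
#' @export
cultivation_crossref <- function(seq_taxa, culture_taxa, pma_taxa = character(0)) {
  seq_taxa <- unique(as.character(seq_taxa))
  culture_taxa <- unique(as.character(culture_taxa))
  pma_taxa <- unique(as.character(pma_taxa))
  both <- intersect(seq_taxa, culture_taxa)
  res <- list(
    both = both,
    seq_only = setdiff(seq_taxa, culture_taxa),
    culture_only = setdiff(culture_taxa, seq_taxa),
    pma_retained = intersect(pma_taxa, union(seq_taxa, culture_taxa)))
  res$counts <- c(n_seq = length(seq_taxa), n_culture = length(culture_taxa),
                  both = length(res$both), seq_only = length(res$seq_only),
                  culture_only = length(res$culture_only),
                  pma_retained = length(res$pma_retained))
  res
}
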