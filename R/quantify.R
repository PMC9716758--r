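# Absolute-abundance quantification via multi-species internal standards or
# qPCR 16S totals, plus spike-in experimental design.

#' Define a multi-species spike-in internal standard
#'
#' An internal standard is a community of known composition (e.g. a commercial
#' mock community of 8 bacteria and 2 yeasts) added to each sample in a known
#' quantity before processing. Knowing each member's input quantity converts
#' read counts to absolute abundances; a designed viable fraction per member
#' additionally calibrates viability (PMA) treatment.
#'
#' @param taxon Character vector of member labels, in the collapsed
#'   lowest-classifiable-rank convention of [collapse_to_lowest_rank()].
#' @param input_quantity Known input per member (cells or 16S gene copies per
#'   sample); all `> 0`. Output units of downstream absolute profiles follow
#'   these units.
#' @param designed_viable_fraction Fraction of each member that is viable by
#'   design, in `[0, 1]`; a commercial standard is effectively all-dead
#'   (fraction 0), a custom half-live mixture has 0.5.
#' @param total_dna_conc Optional spike DNA concentration (ng/uL), used by
#'   [design_spike_volume()].
#' @param top_species_dna_fraction Optional DNA fraction of the most abundant
#'   member, used by [design_spike_volume()].
#' @return A `spike_spec` object (data frame of members plus attributes).
#' @export
spike_spec <- function(taxon, input_quantity,
                       designed_viable_fraction = 0,
                       total_dna_conc = NULL,
                       top_species_dna_fraction = NULL) {
  stopifnot(is.character(taxon), length(taxon) >= 1L)
  if (anyDuplicated(taxon)) stop_bad("duplicate spike member labels")
  if (length(input_quantity) == 1L)
    input_quantity <- rep(input_quantity, length(taxon))
  if (length(designed_viable_fraction) == 1L)
    designed_viable_fraction <- rep(designed_viable_fraction, length(taxon))
  stopifnot(length(input_quantity) == length(taxon),
            length(designed_viable_fraction) == length(taxon))
  if (any(input_quantity <= 0)) stop_bad("input_quantity must be > 0")
  if (any(designed_viable_fraction < 0 | designed_viable_fraction > 1))
    stop_bad("designed_viable_fraction must be in [0, 1]")
  structure(
    data.frame(taxon = taxon, input_quantity = input_quantity,
               designed_viable_fraction = designed_viable_fraction,
               stringsAsFactors = FALSE),
    total_dna_conc = total_dna_conc,
    top_species_dna_fraction = top_species_dna_fraction,
    class = c("spike_spec", "data.frame"))
}

#' Read a spike-in specification from CSV or YAML
#'
#' CSV needs columns `taxon,input_quantity,designed_viable_fraction`; YAML a
#' `members` list with the same fields plus optional `total_dna_conc` and
#' `top_species_dna_fraction`.
#'
#' @param path File path (`.yaml`/`.yml` or CSV).
#' @return A [spike_spec()].
#' @export
read_spike_spec <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (is.null(y$members)) stop_bad("spike YAML needs a `members` list")
    taxon <- vapply(y$members, function(m) as.character(m$taxon), "")
    iq <- vapply(y$members, function(m) as.numeric(m$input_quantity), 0)
    vf <- vapply(y$members, function(m) {
      if (is.null(m$designed_viable_fraction)) 0
      else as.numeric(m$designed_viable_fraction)
    }, 0)
    spike_spec(taxon, iq, vf,
               total_dna_conc = y$total_dna_conc,
               top_species_dna_fraction = y$top_species_dna_fraction)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("taxon", "input_quantity")
    if (!all(need %in% names(df)))
      stop_bad("spike CSV must have columns ", paste(need, collapse = ", "))
    vf <- if ("designed_viable_fraction" %in% names(df))
      df$designed_viable_fraction else 0
    spike_spec(df$taxon, df$input_quantity, vf)
  }
}

#' Tag spike-in members in a profile and warn on plausible native taxa
#'
#' Sets `domain_tag = "spike"` for the spec's members. A spike member that is
#' only classifiable at genus level or above is a plausible native community
#' taxon (spike and native reads are then inseparable), which triggers a
#' warning — the recognizability caveat of internal standards.
#'
#' @param profile A [profile_matrix()].
#' @param spec A [spike_spec()].
#' @return The profile with updated domain tags.
#' @export
tag_spike <- function(profile, spec) {
  stopifnot(inherits(profile, "profile_matrix"), inherits(spec, "spike_spec"))
  hit <- rownames(profile$counts) %in% spec$taxon
  profile$domain_tag[hit] <- "spike"
  shallow <- spec$taxon[!grepl("^s_", spec$taxon)]
  if (length(shallow))
    warning("spike member(s) not resolved to species level; native reads may ",
            "be confounded: ", paste(shallow, collapse = ", "), call. = FALSE)
  profile
}

#' Per-sample copies-per-read scaling factors from the internal standard
#'
#' For each spike member m in sample s, `factor_m = input_quantity_m /
#' reads_m(s)`; the sample's factor is the median (optionally the mean) over
#' members. The median tolerates classifier bias on individual spike taxa.
#' Per-member factors are retained for diagnostics.
#'
#' @param profile A [profile_matrix()] still containing the spike taxa.
#' @param spec A [spike_spec()]; every member must have `> 0` reads in every
#'   sample, otherwise an error names the offenders.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return A `scaling_factors` object: data frame `sample_id,copies_per_read`
#'   with the per-member factor matrix in attribute `per_member`.
#' @export
spike_scaling_factors <- function(profile, spec, aggregate = c("median", "mean")) {
  stopifnot(inherits(profile, "profile_matrix"), inherits(spec, "spike_spec"))
  aggregate <- match.arg(aggregate)
  missing <- setdiff(spec$taxon, rownames(profile$counts))
  if (length(missing))
    stop_bad("spike member(s) absent from profile: ",
             paste(missing, collapse = ", "))
  reads <- profile$counts[spec$taxon, , drop = FALSE]
  zero <- which(reads == 0, arr.ind = TRUE)
  if (nrow(zero))
    stop_bad("spike member(s) with zero reads: ",
             paste(sprintf("%s in %s", rownames(reads)[zero[, 1]],
                           colnames(reads)[zero[, 2]]), collapse = "; "))
  per_member <- spec$input_quantity / reads     # copies per read, member x sample
  agg_fun <- if (aggregate == "median") stats::median else mean
  cpr <- apply(per_member, 2, agg_fun)
  out <- data.frame(sample_id = colnames(reads), copies_per_read = cpr,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, per_member = per_member, aggregate = aggregate,
            class = c("scaling_factors", "data.frame"))
}

#' Absolute abundances from spike-in scaling factors
#'
#' `abs[i, s] = reads[i, s] * copies_per_read[s]` for every non-spike taxon;
#' spike members are removed from the output. Units follow the spike spec's
#' input quantities.
#'
#' @param profile A [profile_matrix()].
#' @param factors Result of [spike_scaling_factors()].
#' @param spec The [spike_spec()] whose members are excluded.
#' @return Numeric matrix (taxa x samples) of absolute abundances.
#' @export
absolute_from_spike <- function(profile, factors, spec) {
  stopifnot(inherits(profile, "profile_matrix"),
            inherits(factors, "scaling_factors"))
  miss <- setdiff(colnames(profile$counts), factors$sample_id)
  if (length(miss))
    stop_bad("no scaling factor for sample(s): ", paste(miss, collapse = ", "))
  cpr <- stats::setNames(factors$copies_per_read, factors$sample_id)
  keep <- !(rownames(profile$counts) %in% spec$taxon)
  counts <- profile$counts[keep, , drop = FALSE]
  sweep(counts, 2, cpr[colnames(counts)], `*`)
}

#' Absolute abundances from relative abundances and qPCR totals
#'
#' Scales each sample's relative abundances (which must sum to 1) by its
#' total 16S rRNA gene copy number. The appropriate route when taxonomic
#' classification is too coarse to recognize spike-in members.
#'
#' @param rel Numeric matrix (taxa x samples) of relative abundances, each
#'   column summing to 1 within `1e-6`.
#' @param qpcr Data frame `sample_id,copies_per_sample` as from [read_qpcr()].
#' @return Numeric matrix of absolute abundances; a sample with 0 total
#'   copies yields zeros with a warning.
#' @export
absolute_from_qpcr <- function(rel, qpcr) {
  rel <- as.matrix(rel)
  miss <- setdiff(colnames(rel), qpcr$sample_id)
  if (length(miss))
    stop_bad("no qPCR total for sample(s): ", paste(miss, collapse = ", "))
  sums <- colSums(rel)
  bad <- abs(sums - 1) >= 1e-6
  if (any(bad))
    stop_bad("relative abundances do not sum to 1 in sample(s): ",
             paste(colnames(rel)[bad], collapse = ", "))
  copies <- stats::setNames(qpcr$copies_per_sample, qpcr$sample_id)[colnames(rel)]
  if (any(copies == 0))
    warning("sample(s) with zero qPCR total: all-zero absolute abundances",
            call. = FALSE)
  sweep(rel, 2, copies, `*`)
}

#' Relative abundances of a profile (per-sample column proportions)
#'
#' @param profile A [profile_matrix()] or counts matrix.
#' @param exclude_spike Drop taxa tagged `spike` before normalizing (only for
#'   `profile_matrix` input).
#' @return Numeric matrix whose columns sum to 1 (all-zero samples stay 0).
#' @export
relative_abundance <- function(profile, exclude_spike = FALSE) {
  counts <- if (inherits(profile, "profile_matrix")) {
    keep <- if (exclude_spike) profile$domain_tag != "spike" else TRUE
    profile$counts[keep, , drop = FALSE]
  } else as.matrix(profile)
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  sweep(counts, 2, tot, `/`)
}

#' Spike volume needed to hit a target DNA fraction
#'
#' Standard-addition design rule: choose the spike volume so that the DNA of
#' the spike's most abundant species approximates a small target fraction
#' (default 1%) of the sample's total DNA —
#' `volume = target_fraction * sample_dna_total_ng /
#'   (spike_dna_conc_ng_per_ul * top_species_fraction)`.
#'
#' @param sample_dna_total_ng Total DNA in the sample (ng), `> 0`.
#' @param spike_dna_conc_ng_per_ul Spike DNA concentration (ng/uL), `> 0`.
#' @param top_species_fraction DNA fraction of the spike's most abundant
#'   member, in `(0, 1]`.
#' @param target_fraction Target fraction of sample DNA, in `(0, 1)`,
#'   default `0.01`.
#' @return Spike volume in uL.
#' @export
design_spike_volume <- function(sample_dna_total_ng, spike_dna_conc_ng_per_ul,
                                top_species_fraction, target_fraction = 0.01) {
  assert_scalar_num(sample_dna_total_ng, "sample_dna_total_ng", 0,
                    strict_lower = TRUE)
  assert_scalar_num(spike_dna_conc_ng_per_ul, "spike_dna_conc_ng_per_ul", 0,
                    strict_lower = TRUE)
  assert_scalar_num(top_species_fraction, "top_species_fraction", 0, 1,
                    strict_lower = TRUE)
  assert_scalar_num(target_fraction, "target_fraction", 0, 1,
                    strict_lower = TRUE, strict_upper = TRUE)
  (target_fraction * sample_dna_total_ng) /
    (spike_dna_conc_ng_per_ul * top_species_fraction)
}
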