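# Taxonomic profile tables: rank-prefixed lineages, read/write, cleaning rules.

RANK_PREFIXES <- c("k", "p", "c", "o", "f", "g", "s")

#' Parse a rank-prefixed lineage string
#'
#' Lineage labels follow the SSU-classifier convention of semicolon-delimited,
#' rank-prefixed names, e.g. `"k_Bacteria;p_Proteobacteria;...;s_Pseudomonas
#' fragi"`. Ranks run kingdom (`k`) through species (`s`) and must be
#' contiguous: a named rank may not appear below an unnamed one.
#'
#' @param x A single lineage string.
#' @return A named character vector whose names are rank prefixes in
#'   `c("k","p","c","o","f","g","s")`, possibly truncated below the deepest
#'   classified rank. An empty string yields a zero-length vector.
#' @examples
#' parse_lineage("k_Bacteria;p_Firmicutes")
#' @export
parse_lineage <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (!nzchar(x)) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  m <- regmatches(parts, regexec("^([kpcofgs])_(.*)$", parts))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop_bad("malformed lineage field(s): ", paste(parts[bad], collapse = ", "))
  ranks <- vapply(m, `[`, "", 2L)
  names_ <- vapply(m, `[`, "", 3L)
  idx <- match(ranks, RANK_PREFIXES)
  if (anyNA(idx) || is.unsorted(idx, strictly = TRUE))
    stop_bad("lineage ranks must appear in k>p>c>o>f>g>s order: ", x)
  if (!identical(idx, seq_along(idx)))
    stop_bad("lineage has a gap below a named rank: ", x)
  stats::setNames(names_, ranks)
}

#' Collapse a lineage to its lowest classifiable rank
#'
#' Profiles are labeled to the lowest (deepest) rank the classifier resolved,
#' so a fully classified lineage becomes e.g. `"s_Pseudomonas fragi"` while a
#' kingdom-only assignment stays `"k_Bacteria"`.
#'
#' @param lineage A named character vector as returned by [parse_lineage()],
#'   or a lineage string.
#' @return A single label `"<rank>_<name>"`, or `"unclassified"` when no rank
#'   is named.
#' @examples
#' collapse_to_lowest_rank("k_Bacteria;p_Proteobacteria;c_Gammaproteobacteria")
#' @export
collapse_to_lowest_rank <- function(lineage) {
  if (is.character(lineage) && is.null(names(lineage)) && length(lineage) == 1L)
    lineage <- parse_lineage(lineage)
  named <- lineage[nzchar(lineage)]
  if (length(named) == 0L) return("unclassified")
  last <- length(named)
  paste0(names(named)[last], "_", named[[last]])
}

lineage_domain <- function(lineage) {
  if (length(lineage) == 0L || !("k" %in% names(lineage))) return("other")
  k <- lineage[["k"]]
  if (k %in% c("Bacteria")) "bacteria"
  else if (k %in% c("Eukaryota", "Eukarya", "Fungi")) "eukaryota"
  else "other"
}

#' Construct a taxonomic profile matrix
#'
#' The central container for gene-centric taxonomic profiles: a taxa-by-sample
#' matrix of non-negative integer read counts, with each taxon carrying its
#' parsed lineage and a domain tag in `{bacteria, eukaryota, spike, other}`.
#'
#' @param counts Integer matrix, taxa in rows (rownames = collapsed labels or
#'   full lineage strings), samples in columns.
#' @param lineages Optional list of parsed lineages, one per row; derived from
#'   rownames when omitted.
#' @param domain_tag Optional character vector of per-taxon domain tags;
#'   derived from the lineage kingdom when omitted.
#' @return A `profile_matrix` object.
#' @export
profile_matrix <- function(counts, lineages = NULL, domain_tag = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_bad("`counts` needs taxon rownames and sample colnames")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop_bad("counts must be finite numbers")
  if (any(counts < 0)) stop_bad("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop_bad("counts must be integers")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  if (is.null(lineages)) {
    lineages <- lapply(rownames(counts), function(lab) {
      if (grepl(";", lab) || grepl("^[kpcofgs]_", lab)) {
        tryCatch(parse_lineage(lab), error = function(e) NULL)
      } else NULL
    })
  }
  # collapse rownames that are full lineage strings
  labels <- vapply(seq_len(nrow(counts)), function(i) {
    if (!is.null(lineages[[i]]) && length(lineages[[i]]) > 0L)
      collapse_to_lowest_rank(lineages[[i]])
    else rownames(counts)[i]
  }, "")
  if (anyDuplicated(labels))
    stop_bad("duplicate taxon labels after collapsing: ",
             paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rownames(counts) <- labels
  if (is.null(domain_tag)) {
    domain_tag <- vapply(lineages, function(l) {
      if (is.null(l)) "other" else lineage_domain(l)
    }, "")
  }
  if (!all(domain_tag %in% c("bacteria", "eukaryota", "spike", "other")))
    stop_bad("domain_tag values must be bacteria/eukaryota/spike/other")
  if (length(domain_tag) != nrow(counts))
    stop_bad("`domain_tag` must have one entry per taxon")
  structure(
    list(counts = counts,
         lineages = stats::setNames(lineages, labels),
         domain_tag = stats::setNames(domain_tag, labels)),
    class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(x$domain_tag)
  cat("domains:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$counts)

#' Read a taxonomic profile from a tab-separated count table
#'
#' Expects a column named `taxon` holding semicolon-delimited rank-prefixed
#' lineages (or already-collapsed labels) followed by one integer column per
#' sample, the export format of SSU-classifier count tables.
#'
#' @param path Path to a TSV file.
#' @return A [profile_matrix()].
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_bad("empty profile file: ", path)
  if (!"taxon" %in% names(df))
    stop_bad("profile file must have a `taxon` column")
  if (ncol(df) < 2L) stop_bad("profile file needs at least one sample column")
  taxa <- as.character(df$taxon)
  if (anyDuplicated(taxa))
    stop_bad("duplicate taxon labels in ", path)
  num <- df[setdiff(names(df), "taxon")]
  if (!all(vapply(num, is.numeric, TRUE)))
    stop_bad("non-numeric count column in ", path)
  counts <- as.matrix(num)
  rownames(counts) <- taxa
  profile_matrix(counts)
}

#' Write a profile matrix to TSV
#'
#' Inverse of [read_profile()]: taxa written as their full lineage string when
#' available, otherwise the collapsed label.
#'
#' @param profile A [profile_matrix()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile_matrix"))
  taxon <- vapply(seq_len(nrow(profile$counts)), function(i) {
    l <- profile$lineages[[i]]
    if (!is.null(l) && length(l) > 0L)
      paste(paste0(names(l), "_", l), collapse = ";")
    else rownames(profile$counts)[i]
  }, "")
  df <- data.frame(taxon = taxon, profile$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove singleton taxa from a profile
#'
#' A singleton is a taxon supported by exactly one read summed across all
#' samples of the table; such taxa are treated as spurious classifier output
#' and dropped before downstream analysis. The operation is idempotent.
#'
#' @param profile A [profile_matrix()].
#' @return The profile without singleton taxa; warns if nothing remains.
#' @export
remove_singletons <- function(profile) {
  stopifnot(inherits(profile, "profile_matrix"))
  totals <- rowSums(profile$counts)
  keep <- totals != 1
  if (!any(keep)) warning("all taxa were singletons; profile is empty")
  profile$counts <- profile$counts[keep, , drop = FALSE]
  profile$lineages <- profile$lineages[keep]
  profile$domain_tag <- profile$domain_tag[keep]
  profile
}

#' Per-sample read fractions by domain
#'
#' @param profile A [profile_matrix()].
#' @return A data frame with one row per sample and columns `sample`,
#'   `bacteria`, `eukaryota`, `spike`, `other`, and `empty` (TRUE when the
#'   sample has zero reads, in which case fractions are 0).
#' @export
domain_fractions <- function(profile) {
  stopifnot(inherits(profile, "profile_matrix"))
  doms <- c("bacteria", "eukaryota", "spike", "other")
  tot <- colSums(profile$counts)
  out <- data.frame(sample = colnames(profile$counts),
                    stringsAsFactors = FALSE)
  for (d in doms) {
    dc <- colSums(profile$counts[profile$domain_tag == d, , drop = FALSE])
    out[[d]] <- ifelse(tot > 0, dc / tot, 0)
  }
  out$empty <- tot == 0
  out
}

#' Eukaryotic read fraction per sample
#'
#' Eukaryotic cells (human and otherwise) compete with bacteria for
#' sequencing depth in built-environment samples; this fraction drives the
#' whole-cell filtration recommendation.
#'
#' @param profile A [profile_matrix()].
#' @return Named numeric vector of fractions in `[0, 1]`, one per sample
#'   (0 for empty samples, which carry an `empty` attribute flag).
#' @export
eukaryote_fraction <- function(profile) {
  df <- domain_fractions(profile)
  structure(stats::setNames(df$eukaryota, df$sample), empty = df$empty)
}

#' Recommend whole-cell filtration from the nonbacterial fraction
#'
#' Filtration to deplete eukaryotic cells costs biomass (a serious loss for
#' low-biomass surface samples) and is only worthwhile when the nonbacterial
#' proportion is large; around 1% it is ineffective or unnecessary. The
#' comparison is strict: a fraction exactly at the threshold does not trigger
#' the recommendation.
#'
#' @param fraction Nonbacterial (by default eukaryotic) read fraction in
#'   `[0, 1]`; vectorized.
#' @param threshold Decision threshold, default `0.01`.
#' @return A data frame with columns `fraction`, `recommend` (logical) and
#'   `rationale`.
#' @export
recommend_filtration <- function(fraction, threshold = 0.01) {
  assert_scalar_num(threshold, "threshold", 0, 1)
  stopifnot(is.numeric(fraction), all(fraction >= 0 & fraction <= 1))
  rec <- fraction > threshold
  data.frame(
    fraction = fraction,
    recommend = rec,
    rationale = ifelse(
      rec,
      sprintf("nonbacterial fraction %.3f exceeds %.3f: filtration may increase bacterial signal", fraction, threshold),
      sprintf("nonbacterial fraction %.3f <= %.3f: filtration unnecessary; biomass loss outweighs gain", fraction, threshold)),
    stringsAsFactors = FALSE)
}

#' Flag library DNA input below the reliable-yield threshold
#'
#' DNA inputs above 11.2 ng reliably produced more than 1e5 raw reads with
#' the tagmentation library preparation used for low-biomass surface samples;
#' inputs at or below it are flagged `low`. Strict comparison.
#'
#' @param dna_ng DNA mass in nanograms; vectorized, must be non-negative.
#' @param threshold_ng Threshold in ng, default `11.2`.
#' @return Character vector in `{"pass", "low"}`.
#' @export
assess_library_input <- function(dna_ng, threshold_ng = 11.2) {
  stopifnot(is.numeric(dna_ng))
  if (any(dna_ng < 0)) stop_bad("`dna_ng` must be non-negative")
  ifelse(dna_ng > threshold_ng, "pass", "low")
}
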