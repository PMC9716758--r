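# Sample metadata, qPCR, and Nonpareil summary tables.

METADATA_FEATURES <- c("location", "building", "study", "country",
                       "touch_frequency", "sample_type", "sampling_method",
                       "sample_pooling")

#' Default controlled vocabulary for the eight metadata features
#'
#' The eight accessible predictor features used throughout the depth model:
#' location, building, study, country, touch frequency, sample type, sampling
#' method and sample pooling. Every feature additionally admits the literal
#' level `"unknown"`, which is how missing values are encoded.
#'
#' @return Named list of character vectors, one per feature.
#' @export
default_metadata_vocabulary <- function() {
  list(
    location        = c("sink", "floor", "bedrail", "keyboard", "door_sill",
                        "monitor"),
    building        = c("bldg_A", "bldg_B", "bldg_C", "bldg_D"),
    study           = paste0("study_", 1:7),
    country         = c("USA", "UK", "Germany"),
    touch_frequency = c("high", "low"),
    sample_type     = c("sink", "surface"),
    sampling_method = c("swab", "wipe", "sink"),
    sample_pooling  = c("pooled", "not_pooled")
  )
}

validate_metadata <- function(df, vocabulary, strict) {
  missing_cols <- setdiff(c("sample_id", METADATA_FEATURES), names(df))
  if (length(missing_cols))
    stop_bad("metadata is missing column(s): ",
             paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_bad("duplicate sample ids in metadata")
  for (f in METADATA_FEATURES) {
    v <- as.character(df[[f]])
    v[is.na(v) | !nzchar(v)] <- "unknown"
    allowed <- c(vocabulary[[f]], "unknown")
    bad <- setdiff(unique(v), allowed)
    if (length(bad)) {
      if (strict)
        stop_bad("unknown level(s) in `", f, "`: ",
                 paste(bad, collapse = ", "))
      warning("recoding unseen level(s) in `", f, "` to \"unknown\": ",
              paste(bad, collapse = ", "), call. = FALSE)
      v[v %in% bad] <- "unknown"
    }
    df[[f]] <- v
  }
  df[c("sample_id", METADATA_FEATURES,
       setdiff(names(df), c("sample_id", METADATA_FEATURES)))]
}

#' Read and validate a sample metadata table
#'
#' @param path CSV with columns `sample_id` plus the eight features of
#'   [default_metadata_vocabulary()].
#' @param vocabulary Controlled vocabulary (named list of allowed levels per
#'   feature); defaults to [default_metadata_vocabulary()].
#' @param strict If `TRUE`, a level outside the vocabulary is an error;
#'   otherwise it is recoded to `"unknown"` with a warning.
#' @return A validated data frame; missing values appear as `"unknown"`.
#' @export
read_metadata <- function(path, vocabulary = default_metadata_vocabulary(),
                          strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df, vocabulary, strict)
}

#' Read per-sample 16S rRNA gene qPCR totals
#'
#' @param path CSV with columns `sample_id,copies_per_sample`; copy numbers
#'   are per whole sample after dilution correction.
#' @return Data frame with validated non-negative copy numbers.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "copies_per_sample")
  if (!all(need %in% names(df)))
    stop_bad("qPCR table must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(df$copies_per_sample)) || any(df$copies_per_sample < 0))
    stop_bad("copies_per_sample must be finite and >= 0")
  if (anyDuplicated(df$sample_id)) stop_bad("duplicate sample ids in qPCR table")
  df[need]
}

#' Read per-sample Nonpareil summaries
#'
#' Each row gives the Nonpareil diversity index `nd` (natural-log bp), the
#' projected effort `lrstar` to reach 95% abundance-weighted average coverage
#' (bp), the attained `coverage` fraction, and optionally a path to a
#' two-column effort/coverage curve file (see [read_coverage_curve()]).
#'
#' @param path TSV with columns `sample_id,nd,lrstar,coverage[,curve_file]`.
#' @param load_curves If `TRUE`, curve files (resolved relative to `path`'s
#'   directory) are read into a `curves` attribute, a named list of
#'   [coverage_curve()] objects.
#' @return Data frame of validated records.
#' @export
read_nonpareil <- function(path, load_curves = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "nd", "lrstar", "coverage")
  if (!all(need %in% names(df)))
    stop_bad("Nonpareil table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_bad("duplicate sample ids in Nonpareil table")
  if (any(!is.finite(df$nd))) stop_bad("nd must be finite")
  has_lr <- !is.na(df$lrstar)
  if (any(df$lrstar[has_lr] <= 0)) stop_bad("lrstar must be > 0 when present")
  if (any(df$coverage < 0 | df$coverage > 1, na.rm = TRUE))
    stop_bad("coverage must be in [0, 1]")
  if (load_curves && "curve_file" %in% names(df)) {
    dir <- dirname(path)
    curves <- lapply(df$curve_file, function(f) {
      if (is.na(f) || !nzchar(f)) return(NULL)
      read_coverage_curve(file.path(dir, f))
    })
    names(curves) <- df$sample_id
    attr(df, "curves") <- curves
  }
  df
}
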