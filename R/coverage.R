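# Conversion between sequencing effort and abundance-weighted average
# coverage along a per-sample Nonpareil curve.

#' Construct a coverage curve
#'
#' An ordered set of (sequencing effort in bp, attained coverage fraction)
#' points from a Nonpareil projection. Effort must be strictly increasing
#' after deduplication and coverage non-decreasing in `[0, 1]`. Conversions
#' interpolate linearly in (ln effort, coverage) space — shape-preserving,
#' exact at nodes, and never extrapolated beyond the last point.
#'
#' @param effort_bp Numeric vector of efforts (bp), `> 0`.
#' @param coverage Numeric vector of coverage fractions.
#' @return A `coverage_curve` data frame.
#' @export
coverage_curve <- function(effort_bp, coverage) {
  stopifnot(is.numeric(effort_bp), is.numeric(coverage),
            length(effort_bp) == length(coverage))
  if (length(effort_bp) < 2L) stop_bad("a curve needs at least 2 points")
  if (any(effort_bp <= 0)) stop_bad("effort must be > 0")
  if (any(coverage < 0 | coverage > 1)) stop_bad("coverage must be in [0, 1]")
  o <- order(effort_bp)
  effort_bp <- effort_bp[o]; coverage <- coverage[o]
  dup <- duplicated(effort_bp)
  if (any(dup)) {
    if (any(tapply(coverage, effort_bp, function(x) diff(range(x)) > 1e-12)))
      stop_bad("duplicated effort with conflicting coverage")
    effort_bp <- effort_bp[!dup]; coverage <- coverage[!dup]
  }
  if (any(diff(coverage) < 0))
    stop_bad("coverage must be non-decreasing with effort")
  structure(data.frame(effort_bp = effort_bp, coverage = coverage),
            class = c("coverage_curve", "data.frame"))
}

#' Read a coverage curve from a two-column TSV
#'
#' @param path TSV with columns `effort_bp,coverage`.
#' @return A [coverage_curve()].
#' @export
read_coverage_curve <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("effort_bp", "coverage")
  if (!all(need %in% names(df)))
    stop_bad("curve file must have columns ", paste(need, collapse = ", "))
  coverage_curve(df$effort_bp, df$coverage)
}

#' Sequencing effort required for a target coverage
#'
#' Inverse lookup along the curve: exact at nodes, monotone linear
#' interpolation in ln(effort) between them. A target on a flat (tied)
#' coverage segment resolves to the smallest effort attaining it. Targets
#' above the curve's maximum observed coverage are refused — the curve is a
#' projection and is not extrapolated.
#'
#' @param curve A [coverage_curve()].
#' @param target Coverage fraction in `(0, max(curve$coverage)]`; must also
#'   be at or above the first node's coverage.
#' @return Effort in bp.
#' @export
effort_at_coverage <- function(curve, target) {
  stopifnot(inherits(curve, "coverage_curve"))
  assert_scalar_num(target, "target", 0, 1, strict_lower = TRUE)
  cmax <- max(curve$coverage)
  if (target > cmax)
    stop_bad("target coverage ", target, " is beyond the curve's projection ",
             "(max ", cmax, ")")
  if (target < curve$coverage[1])
    stop_bad("target coverage ", target, " is below the curve's first point")
  ln_eff <- stats::approx(x = curve$coverage, y = log(curve$effort_bp),
                          xout = target, ties = min)$y
  exp(ln_eff)
}

#' Coverage attained at a given sequencing effort
#'
#' Forward lookup: exact at nodes, monotone linear interpolation in
#' ln(effort) between them; efforts outside the curve range are refused.
#'
#' @param curve A [coverage_curve()].
#' @param effort Effort in bp within the curve's effort range.
#' @return Coverage fraction.
#' @export
coverage_at_effort <- function(curve, effort) {
  stopifnot(inherits(curve, "coverage_curve"))
  assert_scalar_num(effort, "effort", 0, strict_lower = TRUE)
  # tolerate floating-point fuzz from a preceding exp(log(.)) round trip
  lo <- min(curve$effort_bp); hi <- max(curve$effort_bp)
  if (effort >= lo * (1 - 1e-9) && effort < lo) effort <- lo
  if (effort <= hi * (1 + 1e-9) && effort > hi) effort <- hi
  if (effort < min(curve$effort_bp) || effort > max(curve$effort_bp))
    stop_bad("effort ", effort, " is outside the curve range [",
             min(curve$effort_bp), ", ", max(curve$effort_bp), "]")
  stats::approx(x = log(curve$effort_bp), y = curve$coverage,
                xout = log(effort), ties = "ordered")$y
}
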