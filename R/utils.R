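#' @keywords internal
"_PACKAGE"

# internal assertion helpers -------------------------------------------------

stop_bad <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad("`", name, "` must be a single finite number")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_bad("`", name, "` = ", x, " is outside its valid range")
  invisible(x)
}

# derive a stream of child seeds from one user seed, staying in 32-bit range
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) + 1000003L * seq_len(n)) %% .Machine$integer.max
}
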