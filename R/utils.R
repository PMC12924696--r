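#' One-tailed spectral Z threshold
#'
#' Returns the standard-normal deviate used as significance cutoff for
#' one-tailed spectral Z-scores, e.g. 1.64 for p < 0.05 and 2.32 for p < 0.01.
#'
#' @param p One-tailed alpha level.
#' @return Numeric threshold `qnorm(1 - p)`.
#' @export
#' @examples
#' z_threshold(0.05)
z_threshold <- function(p = 0.05) {
  stopifnot(is.numeric(p), p > 0, p < 1)
  qnorm(1 - p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fpvs <- function(...) stop(sprintf(...), call. = FALSE)

warn_fpvs <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
assert_finite_matrix <- function(x, name = "data") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_fpvs("%s must be a numeric matrix (channels x samples)", name)
  if (!all(is.finite(x)))
    stop_fpvs("%s contains non-finite values", name)
  invisible(x)
}

## deterministic child seeds below 2^31, derived from a user seed
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% 2147483629L
}
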