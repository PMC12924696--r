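#' Phase-scramble an image
#'
#' Replaces the Fourier phase of a 2-D intensity array by random phases while
#' preserving the amplitude spectrum exactly, the classic control destroying
#' recognizable structure but keeping second-order image statistics. Random
#' phases are obtained as the phase of the 2-D FFT of white noise, which is
#' conjugate-symmetric by construction so the output is real. Self-conjugate
#' coefficients (DC and Nyquist-type bins), whose phase is constrained to 0 or
#' pi, keep the original phase; in particular the image mean is preserved
#' exactly.
#'
#' Multi-plane (color) images should be scrambled per plane by the caller.
#'
#' @param image Numeric matrix (one intensity plane).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return Numeric matrix of the same dimension.
#' @export
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' scr <- phase_scramble_image(img, seed = 1)
#' all.equal(Mod(fft(img)), Mod(fft(scr)))  # amplitude spectrum preserved
phase_scramble_image <- function(image, seed = 1) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    stop_fpvs("image must be a non-empty numeric matrix")
  nr <- nrow(image); nc <- ncol(image)
  X <- fft(image)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  P <- Arg(fft(matrix(rnorm(nr * nc), nr, nc)))
  ## self-conjugate bins: (-k mod n) == k on both axes
  r <- (nr - (seq_len(nr) - 1)) %% nr == (seq_len(nr) - 1)
  c <- (nc - (seq_len(nc) - 1)) %% nc == (seq_len(nc) - 1)
  self <- outer(r, c, `&`)
  P[self] <- Arg(X)[self]
  Y <- Mod(X) * exp(1i * P)
  Re(fft(Y, inverse = TRUE)) / (nr * nc)
}
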