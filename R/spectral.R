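#' Extract an exact-cycle epoch from a segment
#'
#' Cuts the analysis window containing an exact integer number of oddball
#' cycles (default: 34 s starting 0.833 s after sequence onset, i.e. 34 exact
#' 1-Hz cycles), so that the oddball frequency and all its harmonics fall on
#' exact FFT bins and no spectral leakage occurs under the rectangular window.
#' Offsets are snapped to the nearest sample (0.833 s at 200 Hz is sample 167);
#' the epoch length is exact (6800 samples at 200 Hz).
#'
#' @param segment An `fpvs_segment`.
#' @param start_offset_s Epoch start relative to the segment start (s).
#' @param duration_s Epoch duration (s); must be an integer number of oddball
#'   cycles.
#' @param oddball_hz Oddball frequency (Hz).
#' @return Object of class `fpvs_epoch`.
#' @export
epoch_exact_cycles <- function(segment, start_offset_s = 0.833,
                               duration_s = 34, oddball_hz = 1) {
  cycles <- duration_s * oddball_hz
  if (abs(cycles - round(cycles)) > 1e-9)
    stop_fpvs("duration_s (%g) is not an integer number of oddball cycles",
              duration_s)
  rate <- segment$rate_hz
  i0 <- round(start_offset_s * rate)
  n <- round(duration_s * rate)
  if (i0 + n > ncol(segment$data))
    stop_fpvs("segment too short for requested epoch")
  structure(
    list(data = segment$data[, i0 + seq_len(n), drop = FALSE],
         rate_hz = rate, duration_s = duration_s,
         condition_label = segment$condition_label,
         channel_names = rownames(segment$data)),
    class = "fpvs_epoch")
}

#' Average epochs by condition in the time domain
#'
#' Element-wise mean of the epochs sharing a condition label. Phase-locked
#' components are preserved while non-phase-locked noise is attenuated by
#' about 1/sqrt(n) in amplitude.
#'
#' @param epochs List of `fpvs_epoch` objects of equal shape.
#' @return Named list with one averaged `fpvs_epoch` per condition.
#' @export
average_epochs_by_condition <- function(epochs) {
  if (length(epochs) == 0) stop_fpvs("no epochs to average")
  dims <- vapply(epochs, function(e) dim(e$data), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_fpvs("epoch shapes differ")
  conds <- vapply(epochs, function(e) e$condition_label, character(1))
  out <- list()
  for (cond in unique(conds)) {
    sel <- epochs[conds == cond]
    acc <- sel[[1]]$data
    if (length(sel) > 1)
      for (i in 2:length(sel)) acc <- acc + sel[[i]]$data
    avg <- sel[[1]]
    avg$data <- acc / length(sel)
    avg$n_epochs <- length(sel)
    out[[cond]] <- avg
  }
  out
}

#' Single-sided FFT amplitude spectrum of an epoch
#'
#' Rectangular window (no taper), normalization `2|X_k|/N` for k > 0 and
#' `|X_0|/N` at DC, so a unit-amplitude sinusoid on an exact bin reads 1 and
#' injected microvolt amplitudes are read directly. Bin width is
#' `1/duration_s` (~0.029 Hz for a 34-s epoch).
#'
#' @param epoch An `fpvs_epoch`.
#' @return Object of class `fpvs_spectrum` with fields `amplitudes`
#'   (channels x bins), `freqs_hz`, `bin_width_hz`, `rate_hz`, `kind`.
#' @export
amplitude_spectrum <- function(epoch) {
  n <- ncol(epoch$data)
  nf <- floor(n / 2)
  amps <- matrix(0, nrow(epoch$data), nf + 1)
  for (ch in seq_len(nrow(epoch$data))) {
    X <- fft(epoch$data[ch, ])
    a <- Mod(X[seq_len(nf + 1)]) / n
    a[-1] <- 2 * a[-1]
    amps[ch, ] <- a
  }
  rownames(amps) <- epoch$channel_names
  structure(
    list(amplitudes = amps, bin_width_hz = 1 / epoch$duration_s,
         freqs_hz = (0:nf) / epoch$duration_s, rate_hz = epoch$rate_hz,
         kind = "raw", channel_names = epoch$channel_names,
         condition_label = epoch$condition_label),
    class = "fpvs_spectrum")
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf("<fpvs_spectrum (%s): %d channels x %d bins, %.4f Hz/bin>\n",
              x$kind, nrow(x$amplitudes), ncol(x$amplitudes), x$bin_width_hz))
  invisible(x)
}

#' Frequency-to-bin lookup
#'
#' @param spectrum An `fpvs_spectrum`.
#' @param freq_hz Frequency in Hz.
#' @return Zero-based bin index (DC = 0); errors if the frequency does not
#'   fall on an exact bin within tolerance.
#' @export
bin_at <- function(spectrum, freq_hz) {
  b <- freq_hz / spectrum$bin_width_hz
  if (abs(b - round(b)) > 1e-6)
    stop_fpvs("%g Hz does not fall on an exact bin (width %g Hz)",
              freq_hz, spectrum$bin_width_hz)
  as.integer(round(b))
}

#' Noise-estimation recipes
#'
#' A recipe describes which neighboring bins of a target frequency bin are
#' used to estimate the local noise floor. `side_bins` bins are collected on
#' each side; the `exclude_adjacent` bins immediately flanking the target are
#' dropped; optionally a linear trend fitted on the per-side `detrend_range`
#' offsets is subtracted from the whole neighborhood (including the target);
#' the mean and SD are computed over the per-side `z_range` offsets, after
#' dropping the single global maximum and minimum when `exclude_extremes`.
#'
#' The adult recipe (12 per side, adjacent and max/min excluded) retains 20
#' values; the infant recipe (16 per side, offsets 1-5 for detrending and
#' 6-16 for the Z statistics, adjacent and max/min excluded) retains 30
#' neighbors of which 20 enter the mean/SD.
#'
#' @param side_bins Bins collected per side.
#' @param exclude_adjacent Immediately flanking bins dropped per side.
#' @param exclude_extremes Drop the global max and min of the stats bins.
#' @param detrend_range Per-side offset range (inclusive) for the linear
#'   detrend, or NULL for none.
#' @param z_range Per-side offset range used for the mean/SD.
#' @return Object of class `fpvs_noise_recipe`.
#' @export
noise_recipe <- function(side_bins, exclude_adjacent = 1,
                         exclude_extremes = TRUE, detrend_range = NULL,
                         z_range = c(1, side_bins)) {
  if (z_range[2] > side_bins || z_range[1] < 1)
    stop_fpvs("z_range must lie within side_bins")
  if (!is.null(detrend_range) &&
      (detrend_range[2] > side_bins || detrend_range[1] < 1))
    stop_fpvs("detrend_range must lie within side_bins")
  structure(list(side_bins = side_bins, exclude_adjacent = exclude_adjacent,
                 exclude_extremes = exclude_extremes,
                 detrend_range = detrend_range, z_range = z_range),
            class = "fpvs_noise_recipe")
}

#' @rdname noise_recipe
#' @export
adult_noise_recipe <- function() noise_recipe(side_bins = 12)

#' @rdname noise_recipe
#' @export
infant_noise_recipe <- function() {
  noise_recipe(side_bins = 16, detrend_range = c(1, 5), z_range = c(6, 16))
}

## Core neighborhood statistics. `values`: channels x (2*side_bins + 1)
## matrix, center column = side_bins + 1. Returns per-channel noise mean, sd,
## corrected center amplitude, Z, and bookkeeping.
neighborhood_stats <- function(values, recipe) {
  s <- recipe$side_bins
  if (ncol(values) != 2 * s + 1)
    stop_fpvs("neighborhood must have %d columns", 2 * s + 1)
  offs <- -s:s
  keep <- abs(offs) > recipe$exclude_adjacent
  center_col <- s + 1

  vals <- values
  center <- values[, center_col]

  if (!is.null(recipe$detrend_range)) {
    dsel <- keep & abs(offs) >= recipe$detrend_range[1] &
      abs(offs) <= recipe$detrend_range[2]
    o <- offs[dsel]
    V <- values[, dsel, drop = FALSE]
    om <- mean(o)
    slope <- as.vector(V %*% (o - om)) / sum((o - om)^2)
    intercept <- rowMeans(V) - slope * om
    trend <- outer(slope, offs) + intercept
    vals <- values - trend
    center <- vals[, center_col]
  }

  zsel <- keep & abs(offs) >= recipe$z_range[1] &
    abs(offs) <= recipe$z_range[2]
  Z <- vals[, zsel, drop = FALSE]
  n_ch <- nrow(Z)
  noise_mean <- numeric(n_ch)
  noise_sd <- numeric(n_ch)
  n_used <- integer(n_ch)
  for (ch in seq_len(n_ch)) {
    v <- Z[ch, ]
    if (recipe$exclude_extremes && length(v) > 2) {
      v <- v[-c(which.max(v), which.min(v))]
    }
    noise_mean[ch] <- mean(v)
    noise_sd[ch] <- stats::sd(v)
    n_used[ch] <- length(v)
  }
  corrected <- center - noise_mean
  z <- ifelse(noise_sd == 0, Inf, corrected / noise_sd)
  list(noise_mean = noise_mean, noise_sd = noise_sd,
       corrected = corrected, z = z, zero_sd = noise_sd == 0,
       n_bins_used = n_used,
       n_neighbors = sum(keep & (zsel | (if (is.null(recipe$detrend_range))
         FALSE else (abs(offs) >= recipe$detrend_range[1] &
                       abs(offs) <= recipe$detrend_range[2])))))
}

## Extract the channels x (2s+1) neighborhood of a target bin (0-based).
extract_neighborhood <- function(spectrum, target_bin, recipe) {
  s <- recipe$side_bins
  cols <- target_bin + 1 + (-s:s)  # 1-based matrix columns
  if (cols[1] < 2 || cols[length(cols)] > ncol(spectrum$amplitudes))
    stop_fpvs("target bin %d lacks %d-bin noise margin", target_bin, s)
  spectrum$amplitudes[, cols, drop = FALSE]
}

#' Neighbor-bin noise statistics at a target bin
#'
#' @param spectrum A raw `fpvs_spectrum`.
#' @param target_bin Zero-based bin index (see [bin_at()]).
#' @param recipe An `fpvs_noise_recipe`.
#' @return List with per-channel `noise_mean`, `noise_sd`, `corrected`
#'   (baseline-corrected target amplitude), `z`, `zero_sd` flags and
#'   `n_bins_used` (20 for both shipped recipes).
#' @export
noise_stats <- function(spectrum, target_bin, recipe) {
  neighborhood_stats(extract_neighborhood(spectrum, target_bin, recipe),
                     recipe)
}

#' Baseline-corrected and Z-scored spectra
#'
#' For each requested bin, subtracts the neighbor-bin noise mean (negative
#' values preserved) and divides by the noise SD to obtain the spectral
#' Z-score, per channel. Bins without a full noise margin are NA. To obtain
#' the channel-averaged variant, average the spectrum first with
#' [average_spectrum_channels()].
#'
#' @param spectrum A raw `fpvs_spectrum`.
#' @param recipe An `fpvs_noise_recipe`.
#' @param bins Zero-based bin indices (default: all bins with full margin).
#' @return List of two `fpvs_spectrum` objects: `corrected` and `z`.
#' @export
correct_and_zscore <- function(spectrum, recipe, bins = NULL) {
  if (spectrum$kind != "raw")
    stop_fpvs("correct_and_zscore expects a raw spectrum")
  nb <- ncol(spectrum$amplitudes)
  s <- recipe$side_bins
  if (is.null(bins)) bins <- seq(s + 1, nb - 1 - s)
  corrected <- matrix(NA_real_, nrow(spectrum$amplitudes), nb)
  zmat <- matrix(NA_real_, nrow(spectrum$amplitudes), nb)
  for (b in bins) {
    st <- noise_stats(spectrum, b, recipe)
    corrected[, b + 1] <- st$corrected
    zmat[, b + 1] <- st$z
  }
  rownames(corrected) <- rownames(zmat) <- spectrum$channel_names
  corr <- spectrum; corr$amplitudes <- corrected
  corr$kind <- "baseline-corrected"
  zsp <- spectrum; zsp$amplitudes <- zmat; zsp$kind <- "z"
  list(corrected = corr, z = zsp)
}

#' Average a spectrum over channels
#'
#' @param spectrum An `fpvs_spectrum`.
#' @param channels Channel subset (default all).
#' @return A one-channel `fpvs_spectrum` (channel name `"avg"`).
#' @export
average_spectrum_channels <- function(spectrum, channels = NULL) {
  a <- spectrum$amplitudes
  if (!is.null(channels)) {
    missing <- setdiff(channels, rownames(a))
    if (length(missing) > 0)
      stop_fpvs("channels not in spectrum: %s", paste(missing, collapse = ", "))
    a <- a[channels, , drop = FALSE]
  }
  out <- spectrum
  out$amplitudes <- matrix(colMeans(a), 1, ncol(a),
                           dimnames = list("avg", NULL))
  out$channel_names <- "avg"
  out
}

#' Select significant harmonics of a response
#'
#' Counts, per condition, the consecutive run of harmonics (1, 2, 3, ...)
#' whose group Z-score exceeds the threshold, skipping (without breaking the
#' run) harmonics that coincide with multiples of the other response's
#' fundamental, and stopping at `max_hz`. The longest run over conditions is
#' retained. With a 1-Hz oddball and a 6-Hz base this reproduces the
#' "1-15 Hz excluding 6 and 12" rule; for the 6-Hz general response the 50-Hz
#' cap yields at most 8 harmonics (6-48 Hz).
#'
#' @param group_z_by_condition Matrix (conditions x harmonics) or vector of
#'   group Z-scores at harmonics 1..K of `fundamental_hz`, computed on the
#'   all-channel average spectrum.
#' @param fundamental_hz Fundamental of the response being selected.
#' @param overlap_fundamental_hz Fundamental of the other response whose
#'   harmonics must be skipped, or NULL.
#' @param z_threshold One-tailed significance threshold (default 1.64).
#' @param max_hz Upper frequency bound (default 50 Hz).
#' @return Object of class `fpvs_harmonic_set` with `retained_indices`,
#'   `excluded_overlaps`, `fundamental_hz`, `empty` flag.
#' @export
select_harmonics <- function(group_z_by_condition, fundamental_hz,
                             overlap_fundamental_hz = NULL,
                             z_threshold = 1.64, max_hz = 50) {
  zmat <- if (is.matrix(group_z_by_condition)) group_z_by_condition
          else matrix(group_z_by_condition, nrow = 1)
  k_max_freq <- floor(max_hz / fundamental_hz + 1e-9)
  k_avail <- min(ncol(zmat), k_max_freq)
  is_overlap <- function(k) {
    if (is.null(overlap_fundamental_hz)) return(FALSE)
    r <- (k * fundamental_hz) / overlap_fundamental_hz
    abs(r - round(r)) < 1e-9
  }
  best_k <- 0
  for (cond in seq_len(nrow(zmat))) {
    last_good <- 0
    for (k in seq_len(k_avail)) {
      if (is_overlap(k)) next
      if (!is.na(zmat[cond, k]) && zmat[cond, k] > z_threshold)
        last_good <- k
      else break
    }
    best_k <- max(best_k, last_good)
  }
  ks <- seq_len(best_k)
  overl <- if (best_k > 0) ks[vapply(ks, is_overlap, logical(1))] else integer(0)
  retained <- setdiff(ks, overl)
  structure(list(fundamental_hz = fundamental_hz,
                 retained_indices = retained,
                 excluded_overlaps = overl,
                 empty = length(retained) == 0),
            class = "fpvs_harmonic_set")
}

#' @export
print.fpvs_harmonic_set <- function(x, ...) {
  cat(sprintf("<fpvs_harmonic_set: fundamental %g Hz, %d harmonics [%s]%s>\n",
              x$fundamental_hz, length(x$retained_indices),
              paste(x$retained_indices, collapse = ","),
              if (length(x$excluded_overlaps))
                sprintf(", overlaps excluded [%s]",
                        paste(x$excluded_overlaps, collapse = ",")) else ""))
  invisible(x)
}

#' Sum harmonic chunks into one response quantification
#'
#' Extracts, per retained harmonic, the chunk of `2*side_bins + 1` raw
#' amplitude bins centered on the harmonic, sums the chunks element-wise, and
#' quantifies the summed chunk: the summed baseline-corrected amplitude is
#' the sum of the per-harmonic corrected amplitudes (exact, by linearity of
#' the baseline correction), and the summed Z-score is obtained by applying
#' the noise recipe to the summed chunk itself.
#'
#' @param spectrum A raw `fpvs_spectrum`.
#' @param harmonic_set An `fpvs_harmonic_set`.
#' @param recipe An `fpvs_noise_recipe`.
#' @return Object of class `fpvs_summed_response` with per-channel `amplitude`
#'   (microvolts, baseline-corrected and summed), `z` (summed-chunk Z),
#'   `chunk` (summed raw neighborhood, for ROI-level requantification),
#'   `harmonic_set`, `recipe`.
#' @export
sum_harmonic_chunks <- function(spectrum, harmonic_set, recipe) {
  if (harmonic_set$empty) stop_fpvs("empty harmonic set")
  chunk <- NULL
  amplitude <- 0
  for (k in harmonic_set$retained_indices) {
    b <- bin_at(spectrum, k * harmonic_set$fundamental_hz)
    nb <- extract_neighborhood(spectrum, b, recipe)
    chunk <- if (is.null(chunk)) nb else chunk + nb
    amplitude <- amplitude + neighborhood_stats(nb, recipe)$corrected
  }
  st <- neighborhood_stats(chunk, recipe)
  structure(
    list(amplitude = stats::setNames(amplitude, spectrum$channel_names),
         z = stats::setNames(st$z, spectrum$channel_names),
         chunk = chunk, harmonic_set = harmonic_set, recipe = recipe,
         channel_names = spectrum$channel_names),
    class = "fpvs_summed_response")
}

#' @export
print.fpvs_summed_response <- function(x, ...) {
  cat(sprintf(
    "<fpvs_summed_response: %d channels, %d harmonics, max amplitude %.3f uV (%s)>\n",
    length(x$amplitude), length(x$harmonic_set$retained_indices),
    max(x$amplitude), names(which.max(x$amplitude))))
  invisible(x)
}
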