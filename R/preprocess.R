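#' Construct a segment object
#'
#' A segment is one cropped stimulation sequence: channels x samples at a known
#' rate, labeled by condition, with `t0_s` giving the crop offset from the
#' sequence onset.
#'
#' @param data Channels x samples matrix (microvolts), rownames = channels.
#' @param rate_hz Sampling rate.
#' @param condition_label Condition string.
#' @param t0_s Offset of the first sample from the sequence onset (s).
#' @return Object of class `fpvs_segment`.
#' @export
fpvs_segment <- function(data, rate_hz, condition_label = "stim", t0_s = 0) {
  assert_finite_matrix(data)
  structure(list(data = data, rate_hz = rate_hz,
                 condition_label = condition_label, t0_s = t0_s,
                 channel_names = rownames(data)),
            class = "fpvs_segment")
}

#' @export
print.fpvs_segment <- function(x, ...) {
  cat(sprintf("<fpvs_segment '%s': %d channels x %d samples @ %g Hz>\n",
              x$condition_label, nrow(x$data), ncol(x$data), x$rate_hz))
  invisible(x)
}

## Apply a real, symmetric spectral gain to every channel of a matrix.
## gain_fun(f) is evaluated at the physical frequency of every FFT bin;
## the result is real because the gain is even in frequency.
apply_fft_gain <- function(data, rate_hz, gain_fun) {
  n <- ncol(data)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * rate_hz / n
  g <- gain_fun(f)
  out <- data
  for (ch in seq_len(nrow(data)))
    out[ch, ] <- Re(fft(fft(data[ch, ]) * g, inverse = TRUE)) / n
  out
}

## squared magnitude response of an analog Butterworth bandpass of order n;
## applying it once equals one forward-backward (zero-phase) pass.
butter_bandpass_gain2 <- function(f, low_hz, high_hz, order) {
  w0sq <- low_hz * high_hz
  bw <- high_hz - low_hz
  x <- ifelse(f > 0, (f^2 - w0sq) / (f * bw), Inf)
  1 / (1 + x^(2 * order))
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a zero-phase (forward-backward) Butterworth bandpass per channel.
#' The filter is realized in the frequency domain by multiplying the spectrum
#' with the squared Butterworth magnitude response, which is exactly the
#' transfer function of a forward-backward pass and is free of edge transients
#' and numerical instability at very low band edges.
#'
#' @param x An `fpvs_recording` or `fpvs_segment`.
#' @param low_hz,high_hz Band edges (Hz); must satisfy
#'   `0 < low_hz < high_hz < rate/2`.
#' @param order Butterworth order (default 4).
#' @return Object of the same class, filtered; length unchanged.
#' @export
bandpass_filter <- function(x, low_hz = 0.1, high_hz = 100, order = 4) {
  rate <- x$rate_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate / 2))
    stop_fpvs("band edges must satisfy 0 < low < high < rate/2")
  x$data <- apply_fft_gain(x$data, rate, function(f)
    butter_bandpass_gain2(f, low_hz, high_hz, order))
  x
}

#' Resample a recording to a lower rate
#'
#' Fourier resampling: the spectrum is truncated at the new Nyquist frequency
#' and inverse-transformed at the new length, which preserves in-band
#' sinusoids essentially exactly and is inherently anti-aliasing. Only
#' downsampling is supported.
#'
#' @param x An `fpvs_recording` or `fpvs_segment`.
#' @param target_hz New sampling rate (must be below the current rate).
#' @return Object of the same class at `target_hz`; event times (seconds) are
#'   unchanged.
#' @export
resample_recording <- function(x, target_hz = 200) {
  rate <- x$rate_hz
  if (target_hz >= rate)
    stop_fpvs("upsampling is not supported (target %g >= rate %g)",
              target_hz, rate)
  n_in <- ncol(x$data)
  n_out <- round(n_in * target_hz / rate)
  nf <- floor(n_out / 2)
  out <- matrix(0, nrow(x$data), n_out)
  for (ch in seq_len(nrow(x$data))) {
    X <- fft(x$data[ch, ])
    Y <- complex(length.out = n_out)
    Y[1] <- X[1]
    if (nf >= 1) {
      Y[2:(nf + 1)] <- X[2:(nf + 1)]
      idx <- n_out - seq_len(nf) + 1
      keep <- idx > nf + 1
      Y[idx[keep]] <- Conj(X[2:(nf + 1)][keep])
      if (n_out %% 2 == 0) Y[nf + 1] <- Re(X[nf + 1])
    }
    out[ch, ] <- Re(fft(Y, inverse = TRUE)) / n_in
  }
  rownames(out) <- rownames(x$data)
  x$data <- out
  x$rate_hz <- target_hz
  x
}

#' Crop a recording into fixed-length segments at sequence onsets
#'
#' One segment per event, `duration_s` long, starting at the event onset
#' (snapped to the nearest sample). Segments that would run past the end of
#' the recording are dropped with a warning.
#'
#' @param recording An `fpvs_recording` with events.
#' @param duration_s Segment length in seconds (default 36 s, i.e. the full
#'   sequence plus ~333 ms after the fade-out).
#' @return List of `fpvs_segment` objects labeled by the event labels.
#' @export
crop_segments <- function(recording, duration_s = 36) {
  n_samp <- round(duration_s * recording$rate_hz)
  segs <- list()
  for (i in seq_len(nrow(recording$events))) {
    i0 <- round(recording$events$time_s[i] * recording$rate_hz)
    if (i0 + n_samp > ncol(recording$data)) {
      warn_fpvs("segment %d exceeds recording end; dropped", i)
      next
    }
    segs[[length(segs) + 1]] <- fpvs_segment(
      recording$data[, i0 + seq_len(n_samp), drop = FALSE],
      recording$rate_hz,
      condition_label = as.character(recording$events$label[i]),
      t0_s = 0)
  }
  segs
}

.frontal_central_idx <- function(channel_names) {
  grepl("^(Fp|AF|F|FC|FT|C|T)([z0-9])", channel_names)
}

#' Remove blink-like components from a segment
#'
#' Fits a linear (singular value) decomposition of the segment and flags
#' components whose back-projected contribution exceeds
#' `frontal_threshold_uv` on frontal/central channels, or whose time course
#' correlates above 0.7 with the 0.5-4 Hz envelope of the mean frontal signal.
#' At most `max_components` components (largest-variance first) are removed.
#' The brand of decomposition is deliberately unspecified by contract: the
#' guarantee is ground-truth recovery, not component identity.
#'
#' @param segment An `fpvs_segment` (>= 2 channels, > 10 s).
#' @param max_components Maximum number of components to remove.
#' @param frontal_threshold_uv Back-projection amplitude threshold
#'   (microvolts) on frontal/central channels.
#' @return List with `segment` (corrected) and `report` (removed component
#'   indices, criteria, error flag).
#' @export
remove_blink_components <- function(segment, max_components = 5,
                                    frontal_threshold_uv = 200) {
  d <- segment$data
  if (nrow(d) < 2) stop_fpvs("need at least 2 channels")
  if (ncol(d) / segment$rate_hz <= 10)
    stop_fpvs("segment must be longer than 10 s for a stable decomposition")
  frontal <- .frontal_central_idx(rownames(d))
  if (!any(frontal)) frontal <- rep(TRUE, nrow(d))

  mu <- rowMeans(d)
  dc <- d - mu
  sv <- tryCatch(svd(dc), error = function(e) NULL)
  if (is.null(sv)) {
    return(list(segment = segment,
                report = list(removed = integer(0), error = TRUE)))
  }

  ## blink-band (0.5-4 Hz) frontal envelope
  env <- colMeans(d[frontal, , drop = FALSE])
  env <- as.vector(apply_fft_gain(matrix(env, 1), segment$rate_hz, function(f)
    as.numeric(f >= 0.5 & f <= 4)))

  k <- min(length(sv$d), max_components * 2)
  flagged <- logical(k)
  why <- character(k)
  for (i in seq_len(k)) {
    bp <- outer(sv$u[, i] * sv$d[i], sv$v[, i])
    peak <- max(abs(bp[frontal, , drop = FALSE]))
    r <- suppressWarnings(abs(cor(sv$v[, i], env)))
    if (!is.na(peak) && peak > frontal_threshold_uv) {
      flagged[i] <- TRUE; why[i] <- "frontal_amplitude"
    } else if (!is.na(r) && r > 0.7) {
      flagged[i] <- TRUE; why[i] <- "blink_envelope"
    }
  }
  removed <- which(flagged)
  if (length(removed) > max_components)
    removed <- removed[seq_len(max_components)]  # variance order

  if (length(removed) > 0) {
    recon <- dc
    for (i in removed)
      recon <- recon - outer(sv$u[, i] * sv$d[i], sv$v[, i])
    segment$data <- recon + mu
  }
  list(segment = segment,
       report = list(removed = removed, criteria = why[removed],
                     n_removed = length(removed), error = FALSE))
}

#' Block high-amplitude artifacts by spatial reconstruction
#'
#' Samples exceeding `threshold_uv` in absolute value are artifact-marked.
#' For each affected channel a least-squares spatial operator is estimated
#' from artifact-free samples (regression on the remaining channels) and the
#' marked stretches are replaced by its prediction; unmarked samples are left
#' untouched. Any reconstructed value still exceeding the threshold is clipped
#' and counted in the residual fraction.
#'
#' @param segment An `fpvs_segment` (>= 2 channels).
#' @param threshold_uv Blocking threshold (microvolts), default 500.
#' @return List with `segment` and `report` (per-channel marked fractions,
#'   residual fraction, `unusable` flag when more than half the samples are
#'   marked).
#' @export
artifact_block <- function(segment, threshold_uv = 500) {
  d <- segment$data
  if (nrow(d) < 2) stop_fpvs("need at least 2 channels")
  marked <- abs(d) > threshold_uv
  frac <- mean(marked)
  if (frac > 0.5) {
    return(list(segment = segment,
                report = list(marked_fraction = frac, unusable = TRUE,
                              residual_fraction = NA_real_)))
  }
  if (!any(marked)) {
    return(list(segment = segment,
                report = list(marked_fraction = 0, unusable = FALSE,
                              residual_fraction = 0,
                              channels = character(0))))
  }
  clean_cols <- !apply(marked, 2, any)
  out <- d
  bad_ch <- which(rowSums(marked) > 0)
  for (ch in bad_ch) {
    others <- setdiff(seq_len(nrow(d)), ch)
    cols <- which(clean_cols)
    if (length(cols) > nrow(d) + 10) {
      X <- t(d[others, cols, drop = FALSE])
      y <- d[ch, cols]
      fit <- tryCatch(lm.fit(cbind(1, X), y), error = function(e) NULL)
      tcols <- which(marked[ch, ])
      if (!is.null(fit)) {
        Xa <- t(d[others, tcols, drop = FALSE])
        pred <- cbind(1, Xa) %*% fit$coefficients
        pred[!is.finite(pred)] <- 0
        out[ch, tcols] <- pred
      } else {
        out[ch, tcols] <- sign(d[ch, tcols]) * threshold_uv
      }
    } else {
      out[ch, marked[ch, ]] <- sign(d[ch, marked[ch, ]]) * threshold_uv
    }
  }
  resid <- abs(out) > threshold_uv & marked
  residual_fraction <- sum(resid) / length(out)
  out[resid] <- sign(out[resid]) * threshold_uv
  segment$data <- out
  list(segment = segment,
       report = list(marked_fraction = frac, unusable = FALSE,
                     residual_fraction = residual_fraction,
                     channels = rownames(d)[bad_ch]))
}

#' Interpolate bad channels from their spatial neighbors
#'
#' Replaces each bad channel by the inverse-distance-weighted average of its
#' `k` nearest good channels (positions from the montage).
#'
#' @param segment An `fpvs_segment`.
#' @param bad_channels Character vector of channel names to replace.
#' @param montage An `fpvs_montage` covering the segment's channels.
#' @param k Number of neighbors (default 4).
#' @return The segment with bad channels replaced.
#' @export
interpolate_channels <- function(segment, bad_channels, montage, k = 4) {
  if (length(bad_channels) == 0) return(segment)
  chs <- rownames(segment$data)
  if (!all(bad_channels %in% chs))
    stop_fpvs("bad channels not present in segment")
  good <- setdiff(chs, bad_channels)
  if (length(good) < 3) stop_fpvs("fewer than 3 good channels remain")
  pos <- montage$positions[match(chs, montage$channel_names), , drop = FALSE]
  if (anyNA(pos)) stop_fpvs("segment channels missing from montage")
  for (bc in bad_channels) {
    p0 <- pos[match(bc, chs), ]
    dist <- sqrt(rowSums((pos[match(good, chs), , drop = FALSE] -
                            matrix(p0, length(good), 3, byrow = TRUE))^2))
    nb <- order(dist)[seq_len(min(k, length(good)))]
    w <- 1 / pmax(dist[nb], 1e-9)
    w <- w / sum(w)
    segment$data[bc, ] <-
      as.vector(w %*% segment$data[good[nb], , drop = FALSE])
  }
  segment
}

#' Re-reference to the symmetric custom average
#'
#' The reference is the per-sample mean over the set of channels that either
#' belong to a left/right mirror pair or lie on the midline; channels without
#' a mirror partner and off the midline are excluded from the reference (they
#' would bias signal strength toward one side) but are still re-referenced.
#' After the operation the mean over the reference set is zero at every
#' sample.
#'
#' @param segment An `fpvs_segment`.
#' @param montage An `fpvs_montage`.
#' @return The re-referenced segment.
#' @export
rereference_symmetric_average <- function(segment, montage) {
  ref_chs <- intersect(reference_set(montage), rownames(segment$data))
  if (length(ref_chs) == 0) stop_fpvs("empty reference set")
  ref <- colMeans(segment$data[ref_chs, , drop = FALSE])
  segment$data <- sweep(segment$data, 2, ref)
  segment
}
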