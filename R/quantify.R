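## Fixed ROI channel lists. The face-selective sets follow the
## highest-amplitude + contralateral-partner ranking outcome; the general
## response uses a single middle-occipital cluster.
.ROI_PRESETS <- list(
  adult_face = list(
    rOT = c("P8", "PO8", "P10", "PO10"),
    lOT = c("P7", "PO7", "P9", "PO9"),
    mO  = c("PO3", "PO4", "O1", "Oz", "O2")
  ),
  adult_general = list(
    mO = c("PO4", "PO3", "PO8", "O1", "Oz", "O2")
  ),
  infant_face = list(
    rOT = c("CP6", "P4", "P8", "PO8", "P10"),
    lOT = c("CP5", "P3", "P7", "PO7", "P9"),
    mO  = c("O1", "O2", "PO3", "PO4", "Oz", "POz", "Pz")
  ),
  infant_general = list(
    mO = c("POz", "O1", "Oz", "O2")
  )
)

roi_definition <- function(name, channels, construction) {
  structure(list(name = name, channels = channels,
                 construction = construction),
            class = "fpvs_roi")
}

#' @export
print.fpvs_roi <- function(x, ...) {
  cat(sprintf("<fpvs_roi %s (%s): %s>\n", x$name, x$construction,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Screen a single epoch for a usable steady-state response
#'
#' Infant recordings are retained only when the general visual response is
#' measurable on the raw (non-averaged) epoch: the epoch is kept if at least
#' one spectral Z-score over the screening channels at the screening
#' frequencies exceeds the threshold (default: POz/O1/Oz/O2 at 6 or 12 Hz,
#' Z > 2.32, i.e. p < 0.01 one-tailed, with the infant noise recipe).
#'
#' @param epoch_spectrum Raw `fpvs_spectrum` of a single epoch.
#' @param channels Screening channels.
#' @param freqs_hz Screening frequencies (Hz).
#' @param z_threshold One-tailed Z threshold.
#' @param recipe Noise recipe (default [infant_noise_recipe()]).
#' @return List with `keep`, `max_z`, `max_channel`, `max_freq_hz` and the
#'   full `z_table` (channels x frequencies).
#' @export
screen_epoch <- function(epoch_spectrum, channels = c("POz", "O1", "Oz", "O2"),
                         freqs_hz = c(6, 12), z_threshold = 2.32,
                         recipe = infant_noise_recipe()) {
  missing <- setdiff(channels, epoch_spectrum$channel_names)
  if (length(missing) > 0)
    stop_fpvs("screening channel(s) missing from spectrum: %s",
              paste(missing, collapse = ", "))
  zt <- matrix(NA_real_, length(channels), length(freqs_hz),
               dimnames = list(channels, paste0(freqs_hz, "Hz")))
  for (j in seq_along(freqs_hz)) {
    st <- noise_stats(epoch_spectrum, bin_at(epoch_spectrum, freqs_hz[j]),
                      recipe)
    zt[, j] <- st$z[match(channels, epoch_spectrum$channel_names)]
  }
  imax <- which(zt == max(zt), arr.ind = TRUE)[1, ]
  list(keep = max(zt) > z_threshold, max_z = max(zt),
       max_channel = channels[imax[1]], max_freq_hz = freqs_hz[imax[2]],
       z_table = zt)
}

#' Define regions of interest
#'
#' Three construction modes. `"preset"` returns fixed channel lists
#' (`adult_face`, `adult_general`, `infant_face`, `infant_general`).
#' `"ranked"` ranks channels by group-mean summed baseline-corrected
#' amplitude, takes the top `k`, adds each top channel's left/right mirror
#' partner, and partitions the result into left/right/midline clusters by the
#' sign of the x position (ties broken alphabetically, so the construction is
#' deterministic and permutation-invariant). `"fraction"` returns the top
#' `ceiling(fraction * n_channels)` channels as a single ROI.
#'
#' @param summed_response An `fpvs_summed_response` (group mean), required for
#'   ranked/fraction modes.
#' @param montage An `fpvs_montage`.
#' @param mode `"preset"`, `"ranked"` or `"fraction"`.
#' @param preset Preset name for `mode = "preset"`.
#' @param k Number of top channels for `mode = "ranked"`.
#' @param fraction Fraction of channels for `mode = "fraction"`.
#' @return List of `fpvs_roi` objects.
#' @export
define_rois <- function(summed_response = NULL, montage = NULL,
                        mode = c("preset", "ranked", "fraction"),
                        preset = "adult_face", k = 4, fraction = 0.1) {
  mode <- match.arg(mode)
  if (mode == "preset") {
    if (!preset %in% names(.ROI_PRESETS))
      stop_fpvs("unknown ROI preset '%s'", preset)
    return(lapply(names(.ROI_PRESETS[[preset]]), function(nm)
      roi_definition(nm, .ROI_PRESETS[[preset]][[nm]], "preset")))
  }
  amp <- summed_response$amplitude
  chs <- names(amp)
  ## deterministic ranking: amplitude descending, alphabetical on ties
  ord <- order(-amp, chs)
  if (mode == "fraction") {
    n_top <- ceiling(fraction * length(chs))
    return(list(roi_definition("mO", chs[ord[seq_len(n_top)]], "fraction")))
  }
  top <- chs[ord[seq_len(min(k, length(chs)))]]
  mirrors <- vapply(top, .mirror_name, character(1))
  sel <- sort(unique(c(top, mirrors[!is.na(mirrors) &
                                      mirrors %in% montage$channel_names])))
  x <- montage$positions[match(sel, montage$channel_names), "x"]
  out <- list()
  if (any(x < -1e-9))
    out <- c(out, list(roi_definition("lOT", sel[x < -1e-9], "ranked")))
  if (any(x > 1e-9))
    out <- c(out, list(roi_definition("rOT", sel[x > 1e-9], "ranked")))
  if (any(abs(x) <= 1e-9))
    out <- c(out, list(roi_definition("mO", sel[abs(x) <= 1e-9], "ranked")))
  out
}

#' Quantify a summed response over a region of interest
#'
#' The ROI amplitude is the mean of the per-channel summed baseline-corrected
#' amplitudes; the ROI Z-score is recomputed by applying the noise recipe to
#' the ROI-averaged summed chunk (not by averaging per-channel Z values).
#'
#' @param summed_response An `fpvs_summed_response`.
#' @param roi An `fpvs_roi` or character vector of channel names.
#' @return List with `amplitude` (microvolts) and `z`.
#' @export
roi_response <- function(summed_response, roi) {
  channels <- if (inherits(roi, "fpvs_roi")) roi$channels else roi
  missing <- setdiff(channels, summed_response$channel_names)
  if (length(missing) > 0)
    stop_fpvs("ROI channel(s) missing: %s", paste(missing, collapse = ", "))
  idx <- match(channels, summed_response$channel_names)
  amp <- mean(summed_response$amplitude[idx])
  chunk_avg <- matrix(colMeans(summed_response$chunk[idx, , drop = FALSE]),
                      nrow = 1)
  st <- neighborhood_stats(chunk_avg, summed_response$recipe)
  list(amplitude = amp, z = st$z[1])
}

#' Group and individual significance summary
#'
#' @param individual_z Matrix of per-participant Z-scores
#'   (participants x channels).
#' @param group_z Named numeric vector of group-level Z per channel.
#' @param z_threshold Significance threshold (one-tailed), default 1.64.
#' @param rois Optional list of `fpvs_roi` to summarize over.
#' @return Object of class `fpvs_significance_summary`: per-channel group Z
#'   and significance, per-participant significant-channel counts, and (if
#'   given) per-ROI group Z summaries.
#' @export
significance_summary <- function(individual_z, group_z, z_threshold = 1.64,
                                 rois = NULL) {
  if (z_threshold <= 0) stop_fpvs("z_threshold must be positive")
  if (!is.matrix(individual_z)) individual_z <- rbind(individual_z)
  if (!identical(colnames(individual_z), names(group_z)))
    stop_fpvs("individual and group maps must share channels")
  counts <- rowSums(individual_z > z_threshold, na.rm = TRUE)
  channel_table <- data.frame(
    channel = names(group_z), group_z = as.numeric(group_z),
    significant = as.numeric(group_z) > z_threshold,
    stringsAsFactors = FALSE)
  roi_table <- NULL
  if (!is.null(rois)) {
    roi_table <- do.call(rbind, lapply(rois, function(r) {
      data.frame(roi = r$name,
                 mean_group_z = mean(group_z[r$channels]),
                 n_significant = sum(group_z[r$channels] > z_threshold),
                 n_channels = length(r$channels),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(channel_table = channel_table,
                 participant_counts = counts, roi_table = roi_table,
                 z_threshold = z_threshold),
            class = "fpvs_significance_summary")
}

#' @export
print.fpvs_significance_summary <- function(x, ...) {
  cat(sprintf(
    "<fpvs_significance_summary: %d/%d channels significant at Z > %.2f; mean per-participant count %.1f>\n",
    sum(x$channel_table$significant), nrow(x$channel_table), x$z_threshold,
    mean(x$participant_counts)))
  invisible(x)
}
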