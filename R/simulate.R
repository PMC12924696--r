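#' Construct a raw recording object
#'
#' @param data Channels x samples numeric matrix, in microvolts.
#' @param rate_hz Sampling rate.
#' @param channel_names Character vector, one per row of `data`.
#' @param events data.frame with columns `time_s` and `label` (sequence onsets).
#' @return An object of class `fpvs_recording`.
#' @export
fpvs_recording <- function(data, rate_hz, channel_names,
                           events = data.frame(time_s = numeric(0),
                                               label = character(0))) {
  assert_finite_matrix(data)
  if (rate_hz <= 0) stop_fpvs("rate_hz must be positive")
  if (nrow(data) != length(channel_names))
    stop_fpvs("channel_names length must match rows of data")
  if (anyDuplicated(channel_names)) stop_fpvs("channel names must be unique")
  rownames(data) <- channel_names
  structure(list(data = data, rate_hz = rate_hz,
                 channel_names = channel_names, events = events),
            class = "fpvs_recording")
}

#' @export
print.fpvs_recording <- function(x, ...) {
  cat(sprintf("<fpvs_recording: %d channels x %d samples @ %g Hz, %d events>\n",
              nrow(x$data), ncol(x$data), x$rate_hz, nrow(x$events)))
  invisible(x)
}

#' Steady-state response component
#'
#' One periodic neural response: a harmonic series at multiples of
#' `fundamental_hz` with per-harmonic amplitude (microvolts, as read off the
#' single-sided amplitude spectrum) and phase, projected to the scalp through a
#' per-channel topography weight in 0..1.
#'
#' @param fundamental_hz Fundamental frequency (Hz), e.g. 1 for the oddball
#'   (face-selective) response, 6 for the general visual response.
#' @param harmonic_amplitudes Amplitudes for harmonics 1..K (microvolts).
#' @param topography Per-channel weights in 0..1 (named or positional).
#' @param harmonic_phases Phases in radians (recycled; default 0).
#' @return Object of class `fpvs_component`.
#' @export
steady_state_component <- function(fundamental_hz, harmonic_amplitudes,
                                   topography, harmonic_phases = 0) {
  if (fundamental_hz <= 0) stop_fpvs("fundamental_hz must be positive")
  if (any(harmonic_amplitudes < 0)) stop_fpvs("amplitudes must be >= 0")
  if (all(topography == 0)) stop_fpvs("topography must have a nonzero weight")
  phases <- rep_len(harmonic_phases, length(harmonic_amplitudes))
  structure(list(fundamental_hz = fundamental_hz,
                 harmonic_amplitudes = harmonic_amplitudes,
                 harmonic_phases = phases, topography = topography),
            class = "fpvs_component")
}

#' Noise and artifact model for simulated EEG
#'
#' @param pink_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param noise_scale Per-channel RMS of the background noise (microvolts).
#' @param blink_rate Blink events per minute (300-ms half-cosine, frontal).
#' @param blink_amplitude Peak blink amplitude (microvolts).
#' @param spike_rate Single-sample deflections per minute.
#' @param spike_amplitude Spike amplitude (microvolts).
#' @return Object of class `fpvs_noise_model`.
#' @export
noise_model <- function(pink_exponent = 1, noise_scale = 10,
                        blink_rate = 0, blink_amplitude = 400,
                        spike_rate = 0, spike_amplitude = 800) {
  vals <- c(noise_scale, blink_rate, blink_amplitude, spike_rate,
            spike_amplitude)
  if (any(vals < 0)) stop_fpvs("noise model rates and scales must be >= 0")
  structure(list(pink_exponent = pink_exponent, noise_scale = noise_scale,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 spike_rate = spike_rate, spike_amplitude = spike_amplitude),
            class = "fpvs_noise_model")
}

#' Gaussian scalp topography centred on a reference channel
#'
#' @param montage An `fpvs_montage`.
#' @param center Channel name at which the weight is 1.
#' @param sigma Spatial spread (unit-sphere chord distance).
#' @return Named numeric weights in 0..1.
#' @export
topo_gaussian <- function(montage, center = "Oz", sigma = 0.6) {
  if (!center %in% montage$channel_names)
    stop_fpvs("center channel '%s' not in montage", center)
  p0 <- montage$positions[match(center, montage$channel_names), ]
  d2 <- rowSums((montage$positions -
                   matrix(p0, nrow(montage$positions), 3, byrow = TRUE))^2)
  w <- exp(-d2 / (2 * sigma^2))
  names(w) <- montage$channel_names
  w
}

## 1/f^alpha noise, generated in the frequency domain, one independent
## realization per channel; scaled to the requested per-channel RMS.
pink_noise <- function(n_channels, n_samples, rate_hz, alpha = 1, rms = 1) {
  if (rms == 0 || n_samples < 2)
    return(matrix(0, n_channels, n_samples))
  ## generate at a fast FFT length and truncate; the series is stationary so
  ## truncation only drops samples
  n_fft <- stats::nextn(n_samples, c(2, 3, 5))
  nf <- floor(n_fft / 2)
  f <- seq_len(nf) * rate_hz / n_fft
  gain <- f^(-alpha / 2)
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    re <- rnorm(nf); im <- rnorm(nf)
    spec <- complex(real = re, imaginary = im) * gain
    full <- complex(length.out = n_fft)
    full[2:(nf + 1)] <- spec
    idx <- n_fft - seq_len(nf) + 1
    keep <- idx > nf + 1
    full[idx[keep]] <- Conj(spec[keep])
    if (n_fft %% 2 == 0) full[nf + 1] <- complex(real = re[nf], imaginary = 0)
    x <- Re(fft(full, inverse = TRUE))[seq_len(n_samples)] / n_fft
    out[ch, ] <- x / stats::sd(x) * rms
  }
  out
}

## half-cosine blink template, duration_s long, peak 1
blink_template <- function(rate_hz, duration_s = 0.3) {
  n <- max(2, round(duration_s * rate_hz))
  sin(pi * (seq_len(n) - 1) / (n - 1))
}

#' Simulate a raw FPVS-EEG recording
#'
#' Builds a continuous multichannel recording containing `n_sequences`
#' repetitions of `schedule`, separated by `gap_s` of signal-free background.
#' Each steady-state component contributes a sum of cosines at its harmonic
#' frequencies, scaled per channel by its topography and in time by the
#' schedule's contrast envelope; 1/f background noise and (optionally) blink
#' and spike artifacts are added on top. Event markers are placed at each
#' sequence onset.
#'
#' @param schedule An `fpvs_schedule`.
#' @param components List of `fpvs_component` objects.
#' @param noise An `fpvs_noise_model`.
#' @param montage An `fpvs_montage`.
#' @param rate_hz Acquisition rate (Hz); must exceed twice the highest harmonic.
#' @param n_sequences Number of stimulation sequences.
#' @param seed Integer seed; the recording is reproducible bit-for-bit.
#' @param labels Condition label per sequence (recycled).
#' @param component_scales Optional `n_sequences` x `length(components)` matrix
#'   of per-sequence amplitude multipliers (used by [simulate_cohort()] to vary
#'   trial-level oddball amplitude).
#' @param gap_s Silent padding before, between and after sequences (s).
#' @return List with elements `recording` (an `fpvs_recording`) and `manifest`
#'   (ground truth: component amplitudes per sequence, artifact event times,
#'   seed).
#' @export
simulate_recording <- function(schedule, components, noise, montage,
                               rate_hz = 1000, n_sequences = 1, seed = 1,
                               labels = "stim", component_scales = NULL,
                               gap_s = 2) {
  if (schedule$duration_s <= 0) stop_fpvs("zero-duration schedule")
  max_f <- max(vapply(components, function(co)
    co$fundamental_hz * length(co$harmonic_amplitudes), numeric(1)), 0)
  if (rate_hz < 2 * max_f)
    stop_fpvs("rate_hz (%g) below Nyquist for highest harmonic (%g Hz)",
              rate_hz, max_f)
  n_ch <- length(montage$channel_names)
  if (n_ch < 1) stop_fpvs("montage must have at least one channel")
  if (is.null(component_scales))
    component_scales <- matrix(1, n_sequences, max(1, length(components)))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  n_seq_samp <- round(schedule$duration_s * rate_hz)
  n_gap <- round(gap_s * rate_hz)
  n_total <- n_gap + n_sequences * (n_seq_samp + n_gap)
  data <- matrix(0, n_ch, n_total)

  env <- contrast_envelope(schedule, rate_hz)
  t_seq <- (seq_len(n_seq_samp) - 1) / rate_hz
  onsets <- numeric(n_sequences)
  labels <- rep_len(labels, n_sequences)

  ## harmonic basis per component, computed once (per-sequence amplitude
  ## scaling is a scalar multiple of the same waveform)
  base_wave <- lapply(components, function(co) {
    wave <- numeric(n_seq_samp)
    for (k in seq_along(co$harmonic_amplitudes)) {
      a <- co$harmonic_amplitudes[k]
      if (a == 0) next
      wave <- wave + a * cos(2 * pi * k * co$fundamental_hz * t_seq +
                               co$harmonic_phases[k])
    }
    wave * env
  })
  for (s in seq_len(n_sequences)) {
    i0 <- n_gap + (s - 1) * (n_seq_samp + n_gap)
    onsets[s] <- i0 / rate_hz
    for (ci in seq_along(components)) {
      co <- components[[ci]]
      topo <- rep_len(as.numeric(co$topography), n_ch)
      data[, i0 + seq_len(n_seq_samp)] <-
        data[, i0 + seq_len(n_seq_samp)] +
        outer(topo, base_wave[[ci]] * component_scales[s, ci])
    }
  }

  if (noise$noise_scale > 0)
    data <- data + pink_noise(n_ch, n_total, rate_hz, noise$pink_exponent,
                              noise$noise_scale)

  dur_min <- n_total / rate_hz / 60
  blink_times <- numeric(0)
  if (noise$blink_rate > 0 && noise$blink_amplitude > 0) {
    n_blinks <- stats::rpois(1, noise$blink_rate * dur_min)
    blink_times <- sort(runif(n_blinks, 0, n_total / rate_hz - 0.4))
    if (n_blinks > 0) {
      tpl <- blink_template(rate_hz)
      front <- if ("Fpz" %in% montage$channel_names) "Fpz" else
        montage$channel_names[which.max(montage$positions[, "y"])]
      topo <- topo_gaussian(montage, front, sigma = 0.5)
      for (bt in blink_times) {
        i0 <- round(bt * rate_hz)
        idx <- i0 + seq_along(tpl)
        idx <- idx[idx <= n_total]
        data[, idx] <- data[, idx] +
          noise$blink_amplitude * outer(as.numeric(topo), tpl[seq_along(idx)])
      }
    }
  }

  spikes <- data.frame(time_s = numeric(0), channel = character(0))
  if (noise$spike_rate > 0 && noise$spike_amplitude > 0) {
    n_spikes <- stats::rpois(1, noise$spike_rate * dur_min)
    if (n_spikes > 0) {
      s_idx <- sample.int(n_total, n_spikes)
      s_ch <- sample.int(n_ch, n_spikes, replace = TRUE)
      for (j in seq_len(n_spikes))
        data[s_ch[j], s_idx[j]] <- data[s_ch[j], s_idx[j]] +
          sample(c(-1, 1), 1) * noise$spike_amplitude
      spikes <- data.frame(time_s = (s_idx - 1) / rate_hz,
                           channel = montage$channel_names[s_ch])
    }
  }

  rec <- fpvs_recording(data, rate_hz, montage$channel_names,
                        events = data.frame(time_s = onsets, label = labels,
                                            stringsAsFactors = FALSE))
  manifest <- list(
    seed = seed,
    components = lapply(components, function(co)
      co[c("fundamental_hz", "harmonic_amplitudes", "harmonic_phases")]),
    component_scales = component_scales,
    blink_times = blink_times, spikes = spikes,
    labels = labels, onsets = onsets
  )
  list(recording = rec, manifest = manifest)
}

#' Cohort design for group-level simulations
#'
#' Encodes the between-group and within-condition amplitude structure of the
#' oddball response: per condition-by-group cell means, between-participant and
#' within-participant (trial) variability, and trial counts.
#'
#' @param n_per_group Participants per age group.
#' @param conditions Condition labels (e.g. `c("Classic", "New")`).
#' @param groups Group labels (e.g. `c("young", "old")`).
#' @param oddball_mean_by_cell Matrix `length(conditions)` x `length(groups)`
#'   of cell-mean summed oddball amplitudes (microvolts).
#' @param between_sd Between-participant SD (microvolts).
#' @param within_sd Trial-to-trial SD (microvolts).
#' @param trials_per_condition Trials per condition (>= 2).
#' @param seed Integer seed.
#' @return Object of class `fpvs_cohort_design`.
#' @export
cohort_design <- function(n_per_group = 23,
                          conditions = c("Classic", "New"),
                          groups = c("young", "old"),
                          oddball_mean_by_cell =
                            matrix(c(0.25, 1.10, 0.40, 0.51), 2, 2,
                                   dimnames = list(conditions, groups)),
                          between_sd = 0.25, within_sd = 0.25,
                          trials_per_condition = 4, seed = 1) {
  if (between_sd < 0 || within_sd < 0) stop_fpvs("SDs must be >= 0")
  if (trials_per_condition < 2)
    stop_fpvs("at least 2 trials per condition are required")
  if (n_per_group < 2) stop_fpvs("n_per_group must be >= 2")
  oddball_mean_by_cell <- as.matrix(oddball_mean_by_cell)
  dimnames(oddball_mean_by_cell) <- list(conditions, groups)
  structure(list(n_per_group = n_per_group, conditions = conditions,
                 groups = groups, oddball_mean_by_cell = oddball_mean_by_cell,
                 between_sd = between_sd, within_sd = within_sd,
                 trials_per_condition = trials_per_condition, seed = seed),
            class = "fpvs_cohort_design")
}

#' Simulate a cohort of FPVS-EEG recordings
#'
#' Draws, per participant and trial, a true summed oddball amplitude as
#' cell mean + participant effect (SD `between_sd`) + trial noise (SD
#' `within_sd`), truncated at 0, and synthesizes one recording per participant
#' and condition whose oddball component carries those amplitudes. The oddball
#' harmonic profile is normalized so the noise-free summed response over
#' `oddball_profile` harmonics recovers the drawn amplitude exactly.
#'
#' @param design An `fpvs_cohort_design`.
#' @param montage An `fpvs_montage`.
#' @param schedule An `fpvs_schedule`.
#' @param noise An `fpvs_noise_model`.
#' @param rate_hz Simulation rate (Hz). Simulating directly at the analysis
#'   rate (200 Hz) skips the resampling stage for speed.
#' @param oddball_profile Relative amplitudes of the oddball harmonics.
#' @param general_amplitude Summed amplitude of the 6-Hz general response.
#' @param general_profile Relative amplitudes of the general-response harmonics.
#' @param oddball_center,oddball_sigma Topography of the oddball component
#'   (channel name, spread); defaults to a right occipito-temporal focus.
#' @param gap_s Inter-sequence gap (s).
#' @return List with `participants` (list of per-participant entries holding
#'   `id`, `group` and one `fpvs_recording` per condition) and `manifest`
#'   (data.frame of all true per-trial amplitudes).
#' @export
simulate_cohort <- function(design, montage, schedule,
                            noise = noise_model(noise_scale = 8),
                            rate_hz = 200,
                            oddball_profile = c(1, 0.6, 0.35, 0.2),
                            general_amplitude = 2.8,
                            general_profile = c(1, 0.5, 0.3, 0.15, 0.1, 0.05),
                            oddball_center = NULL, oddball_sigma = 0.8,
                            gap_s = 1) {
  if (!inherits(design, "fpvs_cohort_design")) stop_fpvs("invalid design")
  oddball_hz <- schedule$base_rate / schedule$oddball_period
  odd_prof <- oddball_profile / sum(oddball_profile)
  gen_prof <- general_profile / sum(general_profile)
  if (is.null(oddball_center))
    oddball_center <- if ("PO8" %in% montage$channel_names) "PO8" else
      montage$channel_names[which.min(montage$positions[, "y"])]
  topo_odd <- topo_gaussian(montage, oddball_center, oddball_sigma)
  gen_center <- if ("Oz" %in% montage$channel_names) "Oz" else oddball_center
  topo_gen <- topo_gaussian(montage, gen_center, oddball_sigma)

  participants <- list()
  rows <- list()
  pid <- 0
  for (g in seq_along(design$groups)) {
    for (i in seq_len(design$n_per_group)) {
      pid <- pid + 1
      pseed <- derive_seed(design$seed, pid)
      set.seed(pseed)
      p_eff <- rnorm(1, 0, design$between_sd)
      entry <- list(id = sprintf("P%03d", pid), group = design$groups[g],
                    recordings = list())
      for (cond in design$conditions) {
        cell <- design$oddball_mean_by_cell[cond, design$groups[g]]
        amps <- pmax(0, cell + p_eff +
                       rnorm(design$trials_per_condition, 0, design$within_sd))
        comps <- list(
          steady_state_component(oddball_hz, odd_prof, topo_odd),
          steady_state_component(schedule$base_rate,
                                 general_amplitude * gen_prof, topo_gen)
        )
        scales <- cbind(amps, rep(1, design$trials_per_condition))
        sim <- simulate_recording(
          schedule, comps, noise, montage, rate_hz = rate_hz,
          n_sequences = design$trials_per_condition,
          seed = derive_seed(pseed, match(cond, design$conditions)),
          labels = cond, component_scales = scales, gap_s = gap_s)
        entry$recordings[[cond]] <- sim$recording
        rows[[length(rows) + 1]] <- data.frame(
          participant = entry$id, group = design$groups[g], condition = cond,
          trial = seq_len(design$trials_per_condition), true_amplitude = amps,
          stringsAsFactors = FALSE)
      }
      participants[[pid]] <- entry
    }
  }
  list(participants = participants, manifest = do.call(rbind, rows),
       design = design)
}
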