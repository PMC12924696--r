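## Shared fixtures and independent oracles. Everything here is generated in
## code at test time; no binary fixtures are stored.

## Build an exact-cycle epoch straight from a channels x samples matrix.
make_epoch <- function(data, rate_hz = 200, duration_s = 34,
                       condition = "stim", oddball_hz = 1) {
  seg <- fpvs_segment(data, rate_hz, condition_label = condition)
  epoch_exact_cycles(seg, start_offset_s = 0, duration_s = duration_s,
                     oddball_hz = oddball_hz)
}

## Spectrum of a single-channel time series.
make_spectrum <- function(x, rate_hz = 200, duration_s = 34,
                          channel = "Oz") {
  m <- matrix(x, 1, dimnames = list(channel, NULL))
  amplitude_spectrum(make_epoch(m, rate_hz, duration_s))
}

## A small posterior montage that still contains every channel used by the
## adult and infant ROI presets, the screening rule and a frontal site.
posterior_montage <- function() {
  fpvs_montage(channels = c(
    "Fpz", "Fz", "F3", "F4", "Cz", "CP5", "CP6", "P3", "P4", "P7", "P8",
    "P9", "P10", "Pz", "PO3", "PO4", "PO7", "PO8", "PO9", "PO10", "POz",
    "O1", "Oz", "O2"))
}

## Brute-force Benjamini-Hochberg oracle (independent of stats::p.adjust).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Brute-force oracle for the neighbor-bin noise rules, written directly from
## the exclusion description and independent of the package implementation.
## `neigh`: numeric vector of length 2*side+1, center = target.
noise_oracle <- function(neigh, side, adjacent = 1, extremes = TRUE,
                         detrend = NULL, zrange = c(1, side)) {
  offs <- -side:side
  vals <- neigh
  target <- neigh[side + 1]
  if (!is.null(detrend)) {
    sel <- abs(offs) >= max(detrend[1], adjacent + 1) &
      abs(offs) <= detrend[2]
    fit <- lm(vals[sel] ~ offs[sel])
    pred <- coef(fit)[1] + coef(fit)[2] * offs
    vals <- neigh - pred
    target <- vals[side + 1]
  }
  zsel <- abs(offs) >= max(zrange[1], adjacent + 1) & abs(offs) <= zrange[2]
  v <- vals[zsel]
  if (extremes && length(v) > 2) v <- v[-c(which.max(v), which.min(v))]
  list(mean = mean(v), sd = sd(v), corrected = target - mean(v),
       z = (target - mean(v)) / sd(v), n = length(v))
}

## One noise-free oddball simulation at the analysis rate; returns the raw
## spectrum of the 34-s epoch.
sim_oddball_spectrum <- function(amplitudes, fundamental = 1,
                                 noise_scale = 0, seed = 1,
                                 channel = "Oz", rate = 200) {
  mon <- fpvs_montage(channels = channel)
  sched <- build_sequence_schedule()
  topo <- stats::setNames(1, channel)
  comp <- list(steady_state_component(fundamental, amplitudes, topo))
  sim <- simulate_recording(sched, comp, noise_model(noise_scale = noise_scale),
                            mon, rate_hz = rate, n_sequences = 1, seed = seed,
                            gap_s = 0.5)
  ep <- epoch_exact_cycles(crop_segments(sim$recording, 36)[[1]])
  amplitude_spectrum(ep)
}

harmonic_set_fixture <- function(indices, fundamental = 1) {
  structure(list(fundamental_hz = fundamental, retained_indices = indices,
                 excluded_overlaps = integer(0), empty = length(indices) == 0),
            class = "fpvs_harmonic_set")
}
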