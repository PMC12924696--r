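#' Build a stimulation-sequence schedule
#'
#' Constructs the timing skeleton of one FPVS sequence: stimuli at a fixed base
#' rate with every `oddball_period`-th stimulus carrying the oddball category,
#' and a contrast envelope ramping 0 to 1 over the fade-in, holding 1 during
#' full-contrast stimulation, and ramping back to 0 over the fade-out. With the
#' default parameters of a 6-Hz stream and a 1-Hz oddball this yields a
#' 35.666-s sequence (0.833 s fade-in, 34 s full contrast, 0.833 s fade-out)
#' of 214 stimuli, each on screen for 1/6 s (~167 ms).
#'
#' @param base_rate Stimulation rate in Hz (stimuli per second).
#' @param oddball_period Every n-th stimulus is the oddball (integer >= 2).
#' @param fade_in_s,full_s,fade_out_s Durations of the three sequence phases in
#'   seconds.
#' @return An object of class `fpvs_schedule` with fields `base_rate`,
#'   `oddball_period`, `fade_in_s`, `full_s`, `fade_out_s`, `duration_s`,
#'   `onsets` (s), `oddball_flags` (logical), `contrast` (per stimulus, in
#'   0..1) and `warning_flags` (character).
#' @export
#' @examples
#' sched <- build_sequence_schedule(6, 6, 0.833, 34, 0.833)
#' sched$duration_s   # 35.666
build_sequence_schedule <- function(base_rate = 6, oddball_period = 6,
                                    fade_in_s = 0.833, full_s = 34,
                                    fade_out_s = 0.833) {
  if (!is.numeric(base_rate) || base_rate <= 0)
    stop_fpvs("base_rate must be positive")
  if (oddball_period < 2 || oddball_period != round(oddball_period))
    stop_fpvs("oddball_period must be an integer >= 2")
  if (any(c(fade_in_s, full_s, fade_out_s) < 0))
    stop_fpvs("durations must be >= 0")
  duration <- fade_in_s + full_s + fade_out_s
  if (duration <= 0) stop_fpvs("schedule has zero duration")
  warning_flags <- character(0)
  oddball_hz <- base_rate / oddball_period
  if (abs(full_s * oddball_hz - round(full_s * oddball_hz)) > 1e-9)
    warning_flags <- c(warning_flags, "full_s_not_integer_oddball_cycles")

  n_stim <- round(duration * base_rate)
  onsets <- (seq_len(n_stim) - 1) / base_rate
  flags <- (seq_len(n_stim) %% oddball_period) == 0
  contrast <- rep(1, n_stim)
  if (fade_in_s > 0) {
    ramp <- onsets < fade_in_s
    contrast[ramp] <- onsets[ramp] / fade_in_s
  }
  if (fade_out_s > 0) {
    t_out <- duration - fade_out_s
    ramp <- onsets >= t_out
    contrast[ramp] <- pmax(0, 1 - (onsets[ramp] - t_out) / fade_out_s)
  }
  structure(
    list(base_rate = base_rate, oddball_period = oddball_period,
         fade_in_s = fade_in_s, full_s = full_s, fade_out_s = fade_out_s,
         duration_s = duration, onsets = onsets, oddball_flags = flags,
         contrast = contrast, warning_flags = warning_flags),
    class = "fpvs_schedule"
  )
}

#' @export
print.fpvs_schedule <- function(x, ...) {
  cat(sprintf(
    "<fpvs_schedule: %g Hz base, oddball every %d (%g Hz), %.3f s, %d stimuli (%d oddballs)>\n",
    x$base_rate, x$oddball_period, x$base_rate / x$oddball_period,
    x$duration_s, length(x$onsets), sum(x$oddball_flags)))
  invisible(x)
}

#' Per-sample contrast envelope of a schedule
#'
#' Evaluates the fade-in/full/fade-out contrast ramp at an arbitrary sampling
#' rate, for scaling simulated steady-state responses.
#'
#' @param schedule An `fpvs_schedule`.
#' @param rate_hz Sampling rate.
#' @return Numeric vector of length `round(duration_s * rate_hz)`.
#' @export
contrast_envelope <- function(schedule, rate_hz) {
  n <- round(schedule$duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  env <- rep(1, n)
  if (schedule$fade_in_s > 0)
    env[t < schedule$fade_in_s] <-
      t[t < schedule$fade_in_s] / schedule$fade_in_s
  if (schedule$fade_out_s > 0) {
    t0 <- schedule$duration_s - schedule$fade_out_s
    sel <- t >= t0
    env[sel] <- pmax(0, 1 - (t[sel] - t0) / schedule$fade_out_s)
  }
  env
}
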