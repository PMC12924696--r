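#' Analysis configuration
#'
#' Bundles every tunable of the pipeline. Two shipped presets freeze the
#' published parameterizations: [adult_exp1_config()] (55-channel montage,
#' 0.1-100 Hz Butterworth order 4, 200 Hz, 36-s segments, blink-component
#' removal, 12-bins-per-side noise recipe, Set x Scrambling conditions) and
#' [infant_exp2_config()] (32-channel montage, artifact blocking at
#' +/- 500 microvolts, 16-bins-per-side recipe with linear detrending, epoch
#' screening at Z > 2.32 over POz/O1/Oz/O2 at 6/12 Hz, age groups).
#'
#' @param population `"adult"` or `"infant"`.
#' @param ... Overrides of default fields (see the returned list).
#' @return Object of class `fpvs_config` (a named list).
#' @export
analysis_config <- function(population = c("adult", "infant"), ...) {
  population <- match.arg(population)
  cfg <- list(
    population = population,
    montage = if (population == "adult") "adult_55" else "infant_32",
    filter = list(low_hz = 0.1, high_hz = 100, order = 4),
    resample_hz = 200,
    segment_s = 36,
    epoch = list(offset_s = 0.833, duration_s = 34),
    oddball_hz = 1,
    base_hz = 6,
    recipe = population,
    z_threshold = 1.64,
    max_hz = 50,
    artifact = if (population == "adult")
      list(method = "blink_components", max_components = 5,
           frontal_threshold_uv = 200)
    else list(method = "artifact_blocking", threshold_uv = 500),
    screening = if (population == "infant")
      list(channels = c("POz", "O1", "Oz", "O2"), freqs_hz = c(6, 12),
           z_threshold = 2.32)
    else NULL,
    bad_channels = character(0),
    rois = if (population == "adult")
      list(face = "adult_face", general = "adult_general")
    else list(face = "infant_face", general = "infant_general"),
    stats = list(split_condition = (population == "adult"),
                 bayes_iterations = 2000),
    seed = 1
  )
  cfg <- modifyList(cfg, list(...))
  dur_cycles <- cfg$epoch$duration_s * cfg$oddball_hz
  if (abs(dur_cycles - round(dur_cycles)) > 1e-9)
    stop_fpvs("epoch duration must be an integer number of oddball cycles")
  structure(cfg, class = "fpvs_config")
}

#' @rdname analysis_config
#' @export
adult_exp1_config <- function(...) analysis_config("adult", ...)

#' @rdname analysis_config
#' @export
infant_exp2_config <- function(...) analysis_config("infant", ...)

#' Save / load an analysis configuration (JSON)
#'
#' @param config An `fpvs_config`.
#' @param path JSON file path.
#' @return `load_config` returns the `fpvs_config`; `save_config` returns the
#'   path invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- analysis_config(raw$population)
  raw$screening <- if (is.null(raw$screening)) NULL else
    lapply(raw$screening, unlist)
  cfg <- modifyList(unclass(cfg), raw)
  structure(cfg, class = "fpvs_config")
}

noise_recipe_for <- function(config) {
  if (identical(config$recipe, "infant")) infant_noise_recipe()
  else adult_noise_recipe()
}

## config$montage may be a preset name or an explicit channel vector
resolve_montage <- function(config) {
  if (length(config$montage) > 1) fpvs_montage(channels = config$montage)
  else fpvs_montage(config$montage)
}
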