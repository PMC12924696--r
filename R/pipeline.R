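#' Preprocess one raw recording into cleaned segments
#'
#' Applies the configured chain: Butterworth bandpass, downsampling, cropping
#' into fixed-length segments at sequence onsets, artifact handling (blink
#' component removal for adults, artifact blocking for infants), bad-channel
#' interpolation and symmetric-average re-referencing.
#'
#' @param recording An `fpvs_recording`.
#' @param config An `fpvs_config`.
#' @param montage An `fpvs_montage` (defaults to the configured preset).
#' @return List with `segments` (list of `fpvs_segment`) and `reports`.
#' @export
preprocess_recording <- function(recording, config,
                                 montage = resolve_montage(config)) {
  rec <- recording
  if (!is.null(config$filter) &&
      config$filter$high_hz < rec$rate_hz / 2)
    rec <- bandpass_filter(rec, config$filter$low_hz, config$filter$high_hz,
                           config$filter$order)
  if (!is.null(config$resample_hz) && config$resample_hz < rec$rate_hz)
    rec <- resample_recording(rec, config$resample_hz)
  segments <- crop_segments(rec, config$segment_s)
  reports <- list()
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    rep_i <- list()
    if (identical(config$artifact$method, "blink_components")) {
      res <- remove_blink_components(
        seg, config$artifact$max_components %||% 5,
        config$artifact$frontal_threshold_uv %||% 200)
      seg <- res$segment; rep_i$artifact <- res$report
    } else if (identical(config$artifact$method, "artifact_blocking")) {
      res <- artifact_block(seg, config$artifact$threshold_uv %||% 500)
      seg <- res$segment; rep_i$artifact <- res$report
    }
    if (length(config$bad_channels) > 0)
      seg <- interpolate_channels(seg, config$bad_channels, montage)
    seg <- rereference_symmetric_average(seg, montage)
    segments[[i]] <- seg
    reports[[i]] <- rep_i
  }
  list(segments = segments, reports = reports)
}

## average a list of raw spectra (equal geometry) into one
average_spectra <- function(spectra) {
  acc <- spectra[[1]]
  if (length(spectra) > 1)
    for (i in 2:length(spectra))
      acc$amplitudes <- acc$amplitudes + spectra[[i]]$amplitudes
  acc$amplitudes <- acc$amplitudes / length(spectra)
  acc
}

## Z-scores of the all-channel-average spectrum at harmonics 1..k_max of a
## fundamental
harmonic_z_row <- function(spectrum, fundamental_hz, k_max, recipe) {
  chavg <- average_spectrum_channels(spectrum)
  vapply(seq_len(k_max), function(k) {
    b <- bin_at(chavg, k * fundamental_hz)
    ok <- b + 1 - recipe$side_bins >= 2 &&
      b + 1 + recipe$side_bins <= ncol(chavg$amplitudes)
    if (!ok) return(NA_real_)
    noise_stats(chavg, b, recipe)$z[1]
  }, numeric(1))
}

#' Run the full FPVS analysis pipeline on a cohort
#'
#' Orchestrates preprocessing, epoch extraction (and infant epoch screening),
#' condition averaging, spectral quantification, data-driven harmonic
#' selection at the group level, harmonic summation, ROI quantification and
#' group statistics.
#'
#' @param config An `fpvs_config`.
#' @param cohort Result of [simulate_cohort()], or a compatible list with
#'   `participants` entries holding `id`, `group` and named `recordings`.
#' @param out_dir Optional output directory; when given, result tables are
#'   written as CSV/JSON, stamped with the config hash.
#' @return A results bundle (list) with elements `roi_table`,
#'   `summed_channel_table` (tidy per-channel summed responses), `harmonics`,
#'   `anova`, `posthoc`, `bayes`, `split_half`, `screening_log`,
#'   `significance`, `group_z`, `config_hash`.
#' @export
run_pipeline <- function(config, cohort, out_dir = NULL) {
  if (!inherits(config, "fpvs_config")) stop_fpvs("invalid config")
  montage <- resolve_montage(config)
  recipe <- noise_recipe_for(config)
  screening_log <- list()
  spec_by <- list()       # participant -> condition -> spectrum
  half_spec <- list()     # participant -> condition -> odd/even spectra
  groups <- character(0)

  for (pt in cohort$participants) {
    spec_by[[pt$id]] <- list()
    half_spec[[pt$id]] <- list()
    groups[pt$id] <- pt$group
    for (cond in names(pt$recordings)) {
      pp <- preprocess_recording(pt$recordings[[cond]], config, montage)
      epochs <- lapply(pp$segments, epoch_exact_cycles,
                       start_offset_s = config$epoch$offset_s,
                       duration_s = config$epoch$duration_s,
                       oddball_hz = config$oddball_hz)
      if (!is.null(config$screening)) {
        kept <- logical(length(epochs))
        for (i in seq_along(epochs)) {
          sc <- screen_epoch(amplitude_spectrum(epochs[[i]]),
                             channels = config$screening$channels,
                             freqs_hz = config$screening$freqs_hz,
                             z_threshold = config$screening$z_threshold,
                             recipe = recipe)
          kept[i] <- sc$keep
          screening_log[[length(screening_log) + 1]] <- data.frame(
            participant = pt$id, condition = cond, epoch = i,
            kept = sc$keep, max_z = sc$max_z, channel = sc$max_channel,
            freq_hz = sc$max_freq_hz, stringsAsFactors = FALSE)
        }
        epochs <- epochs[kept]
      }
      if (length(epochs) == 0) next
      avg <- average_epochs_by_condition(epochs)[[1]]
      spec_by[[pt$id]][[cond]] <- amplitude_spectrum(avg)
      if (length(epochs) >= 2) {
        odd <- average_epochs_by_condition(
          epochs[seq(1, length(epochs), by = 2)])[[1]]
        even <- average_epochs_by_condition(
          epochs[seq(2, length(epochs), by = 2)])[[1]]
        half_spec[[pt$id]][[cond]] <-
          list(odd = amplitude_spectrum(odd), even = amplitude_spectrum(even))
      }
    }
  }

  conds <- unique(unlist(lapply(spec_by, names)))
  if (length(conds) == 0) stop_fpvs("no usable epochs in any participant")

  ## group-level harmonic selection on the all-channel average
  k_face <- floor(config$max_hz / config$oddball_hz)
  k_gen <- floor(config$max_hz / config$base_hz)
  z_face <- matrix(NA_real_, length(conds), k_face)
  z_gen <- matrix(NA_real_, length(conds), k_gen)
  group_spec <- list()
  for (ci in seq_along(conds)) {
    sl <- Filter(Negate(is.null),
                 lapply(spec_by, function(x) x[[conds[ci]]]))
    group_spec[[conds[ci]]] <- average_spectra(sl)
    z_face[ci, ] <- harmonic_z_row(group_spec[[conds[ci]]],
                                   config$oddball_hz, k_face, recipe)
    z_gen[ci, ] <- harmonic_z_row(group_spec[[conds[ci]]],
                                  config$base_hz, k_gen, recipe)
  }
  face_set <- select_harmonics(z_face, config$oddball_hz, config$base_hz,
                               config$z_threshold, config$max_hz)
  gen_set <- select_harmonics(z_gen, config$base_hz, NULL,
                              config$z_threshold, config$max_hz)

  rois_face <- define_rois(mode = "preset", preset = config$rois$face)
  rois_gen <- define_rois(mode = "preset", preset = config$rois$general)

  ## per-participant summed responses and ROI table
  rows <- list()
  chan_rows <- list()
  indiv_z <- list(face = list(), general = list())
  for (pid in names(spec_by)) {
    for (cond in names(spec_by[[pid]])) {
      sp <- spec_by[[pid]][[cond]]
      for (resp in c("face", "general")) {
        hset <- if (resp == "face") face_set else gen_set
        if (hset$empty) next
        sr <- sum_harmonic_chunks(sp, hset, recipe)
        if (resp == "face") indiv_z$face[[paste(pid, cond)]] <- sr$z
        else indiv_z$general[[paste(pid, cond)]] <- sr$z
        chan_rows[[length(chan_rows) + 1]] <- data.frame(
          participant = pid, group = unname(groups[pid]), condition = cond,
          response = resp, channel = names(sr$amplitude),
          amplitude = unname(sr$amplitude), z = unname(sr$z),
          stringsAsFactors = FALSE)
        rois <- if (resp == "face") rois_face else rois_gen
        for (roi in rois) {
          rr <- roi_response(sr, roi)
          rows[[length(rows) + 1]] <- data.frame(
            participant = pid, group = unname(groups[pid]), condition = cond,
            response = resp, roi = roi$name, amplitude = rr$amplitude,
            z = rr$z, stringsAsFactors = FALSE)
        }
      }
    }
  }
  roi_table <- do.call(rbind, rows)
  rownames(roi_table) <- NULL

  ## group summed response and significance per condition (face)
  group_z <- list()
  significance <- list()
  for (cond in conds) {
    if (face_set$empty) break
    sr_g <- sum_harmonic_chunks(group_spec[[cond]], face_set, recipe)
    group_z[[cond]] <- sr_g$z
    zm <- do.call(rbind, indiv_z$face[grepl(paste0(" ", cond, "$"),
                                            names(indiv_z$face))])
    if (!is.null(zm) && nrow(zm) > 0) {
      colnames(zm) <- names(sr_g$z)
      significance[[cond]] <- significance_summary(
        zm, sr_g$z, config$z_threshold, rois_face)
    }
  }

  ## statistics on the face response (and Set effect on the general response)
  anova_tables <- list(); posthoc <- NULL; bayes <- NULL; split_half <- NULL
  n_groups <- length(unique(groups))
  face_tab <- roi_table[roi_table$response == "face", , drop = FALSE]
  gen_tab <- roi_table[roi_table$response == "general", , drop = FALSE]
  complete_face <- !is.null(face_tab) && nrow(face_tab) > 0 &&
    all(table(face_tab$participant) == length(conds) * length(rois_face))
  if (complete_face && length(conds) >= 2 &&
      length(unique(face_tab$participant)) >= 4) {
    if (isTRUE(config$stats$split_condition) &&
        all(grepl("_", face_tab$condition))) {
      parts <- strsplit(face_tab$condition, "_")
      face_tab$set <- vapply(parts, `[`, "", 1)
      face_tab$scrambling <- vapply(parts, `[`, "", 2)
      mean_roi <- aggregate(amplitude ~ participant + set + scrambling,
                            face_tab, mean)
      anova_tables$face <- rm_anova(mean_roi, "amplitude", "participant",
                                    within = c("set", "scrambling"))
    } else {
      anova_tables$face <- rm_anova(
        face_tab, "amplitude", "participant",
        within = c("condition", "roi"),
        between = if (n_groups > 1) "group" else NULL)
    }
    ## paired contrasts between conditions on the ROI-mean amplitude
    mr <- aggregate(amplitude ~ participant + condition, face_tab, mean)
    cell <- do.call(cbind, lapply(conds, function(cc)
      mr$amplitude[mr$condition == cc][order(mr$participant[mr$condition == cc])]))
    colnames(cell) <- conds
    cmb <- utils::combn(conds, 2, simplify = FALSE)
    posthoc <- paired_contrasts(cell, cmb)
    if ((config$stats$bayes_iterations %||% 0) > 0) {
      bayes <- bayes_rm_anova(mr, effects = "condition", dv = "amplitude",
                              participant = "participant",
                              iterations = config$stats$bayes_iterations,
                              seed = config$seed)
    }
  }
  if (!is.null(gen_tab) && nrow(gen_tab) > 0 && length(conds) >= 2) {
    mg <- aggregate(amplitude ~ participant + condition + group, gen_tab,
                    mean)
    if (all(table(mg$participant) == length(conds)) &&
        length(unique(mg$participant)) >= 4) {
      anova_tables$general <- rm_anova(
        mg, "amplitude", "participant", within = "condition",
        between = if (n_groups > 1) "group" else NULL)
    }
  }

  ## split-half reliability of the face response (ROI-mean amplitude)
  if (!face_set$empty) {
    sh_rows <- list()
    face_chans <- unique(unlist(lapply(rois_face, `[[`, "channels")))
    vals <- list()
    for (cond in conds) {
      odd_v <- c(); even_v <- c()
      for (pid in names(half_spec)) {
        hs <- half_spec[[pid]][[cond]]
        if (is.null(hs)) next
        so <- sum_harmonic_chunks(hs$odd, face_set, recipe)
        se <- sum_harmonic_chunks(hs$even, face_set, recipe)
        odd_v[pid] <- mean(so$amplitude[face_chans])
        even_v[pid] <- mean(se$amplitude[face_chans])
      }
      if (length(odd_v) >= 4) {
        sh <- split_half_reliability(odd_v, even_v)
        vals[[cond]] <- (odd_v + even_v) / 2
        sh_rows[[cond]] <- data.frame(condition = cond, r = sh$r, p = sh$p,
                                      n = sh$n, stringsAsFactors = FALSE)
      }
    }
    if (length(sh_rows) > 0) {
      split_half <- do.call(rbind, sh_rows)
      split_half$p_fdr <- fdr_adjust(split_half$p)
      if (length(sh_rows) >= 2) {
        c12 <- conds[conds %in% names(vals)][1:2]
        shared <- intersect(names(vals[[c12[1]]]), names(vals[[c12[2]]]))
        if (length(shared) >= 10) {
          r12 <- cor(vals[[c12[1]]][shared], vals[[c12[2]]][shared])
          cmpr <- compare_dependent_correlations(
            split_half$r[split_half$condition == c12[1]],
            split_half$r[split_half$condition == c12[2]],
            r12, length(shared))
          attr(split_half, "comparison") <- cmpr
        }
      }
    }
  }

  bundle <- list(
    roi_table = roi_table,
    summed_channel_table = if (length(chan_rows))
      do.call(rbind, chan_rows) else NULL,
    harmonics = list(face = face_set, general = gen_set),
    group_z = group_z,
    significance = significance,
    anova = anova_tables,
    posthoc = posthoc,
    bayes = bayes,
    split_half = split_half,
    screening_log = if (length(screening_log))
      do.call(rbind, screening_log) else NULL,
    config = config,
    config_hash = config_hash(unclass(config))
  )
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' Write a results bundle to disk
#'
#' @param bundle Result of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { df$config_hash <- bundle$config_hash; df }
  utils::write.csv(stamp(bundle$roi_table),
                   file.path(out_dir, "roi_table.csv"), row.names = FALSE)
  if (!is.null(bundle$summed_channel_table))
    utils::write.csv(stamp(bundle$summed_channel_table),
                     file.path(out_dir, "summed_channel_table.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$screening_log))
    utils::write.csv(stamp(bundle$screening_log),
                     file.path(out_dir, "screening_log.csv"),
                     row.names = FALSE)
  for (nm in names(bundle$anova))
    utils::write.csv(stamp(as.data.frame(bundle$anova[[nm]])),
                     file.path(out_dir, paste0("anova_", nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(bundle$posthoc))
    utils::write.csv(stamp(bundle$posthoc),
                     file.path(out_dir, "posthoc.csv"), row.names = FALSE)
  if (!is.null(bundle$bayes))
    utils::write.csv(stamp(bundle$bayes),
                     file.path(out_dir, "bayes.csv"), row.names = FALSE)
  if (!is.null(bundle$split_half))
    utils::write.csv(stamp(as.data.frame(bundle$split_half)),
                     file.path(out_dir, "split_half.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(face = unclass(bundle$harmonics$face),
         general = unclass(bundle$harmonics$general),
         config_hash = bundle$config_hash),
    file.path(out_dir, "harmonics.json"), auto_unbox = TRUE, digits = NA)
  save_config(bundle$config, file.path(out_dir, "config.json"))
  invisible(out_dir)
}
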