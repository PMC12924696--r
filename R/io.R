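pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)
}

#' Write a recording to EDF
#'
#' European Data Format, 16-bit, physical units microvolts, one-second data
#' records (the final record is zero-padded when the signal length is not a
#' whole number of seconds). Event markers are written to a companion
#' tab-separated table `<path>.events.tsv` with columns `onset_s` and
#' `label`.
#'
#' @param recording An `fpvs_recording`; `rate_hz` must be an integer.
#' @param path Output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  d <- recording$data
  rate <- recording$rate_hz
  if (abs(rate - round(rate)) > 1e-9)
    stop_fpvs("EDF writer requires an integer sampling rate")
  rate <- as.integer(round(rate))
  ns <- nrow(d)
  n_rec <- ceiling(ncol(d) / rate)
  if (ncol(d) < n_rec * rate)
    d <- cbind(d, matrix(0, ns, n_rec * rate - ncol(d)))

  pmax_ <- apply(abs(d), 1, max)
  pmax_ <- ifelse(pmax_ <= 0, 1, pmax_ * 1.0001)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X", 80), pad_field("fpvs", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  f <- function(vals, w) writeChar(paste(vapply(vals, pad_field, "", w),
                                         collapse = ""), con, eos = NULL)
  f(recording$channel_names, 16)
  f(rep("", ns), 80)
  f(rep("uV", ns), 8)
  f(sprintf("%.6g", -pmax_), 8)
  f(sprintf("%.6g", pmax_), 8)
  f(rep("-32768", ns), 8)
  f(rep("32767", ns), 8)
  f(rep("", ns), 80)
  f(rep(rate, ns), 8)
  f(rep("", ns), 32)

  scale <- 32767 / pmax_
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * rate + seq_len(rate)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round(d[ch, idx] * scale[ch]))
      dig <- pmax(pmin(dig, 32767L), -32768L)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  if (nrow(recording$events) > 0)
    utils::write.table(
      data.frame(onset_s = recording$events$time_s,
                 label = recording$events$label),
      paste0(path, ".events.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  invisible(path)
}

#' Read an EDF recording
#'
#' Supports the plain 16-bit EDF layout written by [write_edf()] (equal
#' sampling rate across signals). Events are loaded from
#' `<path>.events.tsv` when present.
#'
#' @param path EDF file path.
#' @return An `fpvs_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1)
    stop_fpvs("mixed per-signal rates are not supported")
  rate <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      data[ch, (r - 1) * spr[ch] + seq_len(spr[ch])] <- phys
    }
  }
  ev_path <- paste0(path, ".events.tsv")
  events <- if (file.exists(ev_path))
    utils::read.delim(ev_path, stringsAsFactors = FALSE,
                      col.names = c("time_s", "label"))
  else data.frame(time_s = numeric(0), label = character(0))
  fpvs_recording(data, rate, labels, events)
}

.parse_ini <- function(lines) {
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln) && section != "") {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <-
        trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording (read-only support)
#'
#' Parses the `.vhdr`/`.vmrk`/binary triplet: multiplexed binary data in
#' `INT_16` (scaled by the per-channel resolution) or `IEEE_FLOAT_32`.
#' Stimulus markers become events (`time_s`, `label`).
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An `fpvs_recording`.
#' @export
read_brainvision <- function(vhdr_path) {
  hdr <- .parse_ini(readLines(vhdr_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop_fpvs("not a BrainVision header: %s", vhdr_path)
  if (!is.null(ci$DataFormat) && toupper(ci$DataFormat) != "BINARY")
    stop_fpvs("only BINARY BrainVision data are supported")
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  n_ch <- as.integer(ci$NumberOfChannels)
  rate <- 1e6 / as.numeric(ci$SamplingInterval)
  dirn <- dirname(vhdr_path)
  data_path <- file.path(dirn, ci$DataFile)
  fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")

  chinfo <- hdr[["Channel Infos"]]
  names_res <- lapply(seq_len(n_ch), function(i) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",")[[1]]
    list(name = parts[1],
         res = if (length(parts) >= 3 && nzchar(parts[3]))
           as.numeric(parts[3]) else 1)
  })
  ch_names <- vapply(names_res, `[[`, "", "name")
  res <- vapply(names_res, `[[`, numeric(1), "res")

  sz <- file.info(data_path)$size
  if (fmt == "INT_16") {
    n_total <- sz / 2
    raw_v <- readBin(data_path, "integer", n = n_total, size = 2,
                     endian = "little")
  } else if (fmt == "IEEE_FLOAT_32") {
    n_total <- sz / 4
    raw_v <- readBin(data_path, "numeric", n = n_total, size = 4,
                     endian = "little")
  } else stop_fpvs("unsupported BinaryFormat '%s'", fmt)
  n_samp <- floor(n_total / n_ch)
  if (orientation == "MULTIPLEXED") {
    data <- matrix(raw_v[seq_len(n_ch * n_samp)], n_ch, n_samp)
  } else {
    data <- t(matrix(raw_v[seq_len(n_ch * n_samp)], n_samp, n_ch))
  }
  data <- data * res

  events <- data.frame(time_s = numeric(0), label = character(0))
  if (!is.null(ci$MarkerFile)) {
    mrk_path <- file.path(dirn, ci$MarkerFile)
    if (file.exists(mrk_path)) {
      mk <- .parse_ini(readLines(mrk_path, warn = FALSE))[["Marker Infos"]]
      if (!is.null(mk)) {
        rows <- lapply(mk, function(v) {
          parts <- strsplit(v, ",")[[1]]
          if (length(parts) < 3) return(NULL)
          data.frame(time_s = (as.numeric(parts[3]) - 1) / rate,
                     label = trimws(parts[2]), stringsAsFactors = FALSE)
        })
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows)) events <- do.call(rbind, rows)
      }
    }
  }
  fpvs_recording(data, rate, ch_names, events)
}

## FNV-1a hash of a string; used to stamp outputs with a config fingerprint.
config_hash <- function(x) {
  s <- if (is.character(x) && length(x) == 1) x else
    jsonlite::toJSON(x, auto_unbox = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
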