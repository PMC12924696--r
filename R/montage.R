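## Idealized spherical 10-10 electrode geometry.
##
## Electrodes live on a unit sphere. Midline sites sit on the sagittal arc at
## 18-degree (10%) steps from the vertex; the outer "10% ring" (Fp1/2, F7/8,
## T7/8, P7/8, O1/2 and intermediate ring sites) is the circle 18 degrees above
## the equator; P9/P10-type sites sit on the equator below their ring partner.
## Interior sites are placed by spherical interpolation between the midline
## site of their row and the ring site, at 1/4 steps. This reproduces the
## qualitative layout of a 10-10 cap; exact digitized positions are not needed
## because positions are only used for distance-based interpolation and
## left/right clustering.

# row -> c(midline inclination deg, midline azimuth deg, ring azimuth deg)
.TEN10_ROWS <- list(
  Fp = c(72, 0, 18), AF = c(54, 0, 36), F = c(36, 0, 54), FC = c(18, 0, 72),
  C = c(0, 0, 90), CP = c(18, 180, 108), P = c(36, 180, 126),
  PO = c(54, 180, 144), O = c(72, 180, 162)
)

.polar_to_xyz <- function(incl_deg, az_deg) {
  i <- incl_deg * pi / 180
  a <- az_deg * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

.slerp <- function(p0, p1, t) {
  w <- acos(max(-1, min(1, sum(p0 * p1))))
  if (w < 1e-12) return(p0)
  (sin((1 - t) * w) * p0 + sin(t * w) * p1) / sin(w)
}

## Position of a single 10-10 label on the unit sphere.
.ten10_position <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+?)(z|[0-9]+)$", name))[[1]]
  if (length(m) != 3) stop_fpvs("cannot parse 10-10 channel name '%s'", name)
  lab <- m[2]; idx <- m[3]
  row_key <- switch(lab,
    FT = "FC", T = "C", TP = "CP",
    lab)
  if (is.null(.TEN10_ROWS[[row_key]]))
    stop_fpvs("unknown 10-10 row in channel name '%s'", name)
  row <- .TEN10_ROWS[[row_key]]
  if (idx == "z") return(.polar_to_xyz(row[1], row[2]))
  n <- as.integer(idx)
  side <- if (n %% 2 == 1) -1 else 1          # odd = left
  col <- if (lab %in% c("FT", "T", "TP")) 4L
         else if (lab %in% c("Fp", "O")) 4L   # rows with ring sites only
         else ceiling(n / 2)
  if (n >= 9) col <- 5L
  ring_az <- side * row[3]
  if (col == 4L) return(.polar_to_xyz(72, ring_az))
  if (col == 5L) return(.polar_to_xyz(90, ring_az))
  .slerp(.polar_to_xyz(row[1], row[2]), .polar_to_xyz(72, ring_az), col / 4)
}

.mirror_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+?)(z|[0-9]+)$", name))[[1]]
  if (length(m) != 3 || m[3] == "z") return(NA_character_)
  n <- as.integer(m[3])
  paste0(m[2], if (n %% 2 == 1) n + 1 else n - 1)
}

.ADULT_55 <- c(
  "Fp1", "Fpz", "Fp2", "AF7", "AF8",
  "F7", "F3", "F1", "Fz", "F2", "F4", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C3", "C1", "C2", "C4", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P3", "P1", "Pz", "P2", "P4", "P8", "P9", "P10",
  "PO7", "PO3", "POz", "PO4", "PO8", "PO9", "PO10",
  "O1", "Oz", "O2"
)

.INFANT_32 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "T7", "C3", "C4", "T8",
  "CP5", "CP6", "P7", "P3", "Pz", "P4", "P8", "P9", "P10",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2"
)

#' Montage presets and construction
#'
#' Builds a montage object holding channel names, idealized 3-D positions on a
#' unit sphere, left/right mirror pairs (derived from 10-10 odd/even digit
#' labels) and the midline channel set. Two presets are shipped: an adult
#' 55-recording-channel and an infant 32-recording-channel 10-10 subset, both
#' containing every posterior channel used by the region-of-interest presets
#' (P7/P8, PO7/PO8, P9/P10, PO9/PO10 where applicable, PO3/PO4, O1/Oz/O2, POz,
#' Pz, CP5/CP6, P3/P4).
#'
#' @param preset `"adult_55"` or `"infant_32"`, ignored when `channels` given.
#' @param channels Optional character vector of 10-10 channel names.
#' @return An object of class `fpvs_montage` with elements `channel_names`,
#'   `positions` (n x 3 matrix), `mirror_pairs` (data.frame `left`, `right`)
#'   and `midline` (character).
#' @export
#' @examples
#' m <- fpvs_montage("infant_32")
#' length(m$channel_names)
fpvs_montage <- function(preset = c("adult_55", "infant_32"), channels = NULL) {
  if (is.null(channels)) {
    preset <- match.arg(preset)
    channels <- if (preset == "adult_55") .ADULT_55 else .INFANT_32
  } else {
    preset <- "custom"
  }
  if (anyDuplicated(channels)) stop_fpvs("duplicate channel names in montage")
  pos <- t(vapply(channels, .ten10_position, numeric(3)))
  colnames(pos) <- c("x", "y", "z")
  mirror <- vapply(channels, .mirror_name, character(1))
  in_set <- !is.na(mirror) & mirror %in% channels
  left <- channels[in_set & pos[, "x"] < 0]
  pairs <- data.frame(left = left, right = unname(mirror[left]),
                      stringsAsFactors = FALSE)
  midline <- channels[grepl("z$", channels)]
  structure(
    list(preset = preset, channel_names = channels, positions = pos,
         mirror_pairs = pairs, midline = midline),
    class = "fpvs_montage"
  )
}

#' @export
print.fpvs_montage <- function(x, ...) {
  cat(sprintf("<fpvs_montage '%s': %d channels, %d mirror pairs, %d midline>\n",
              x$preset, length(x$channel_names), nrow(x$mirror_pairs),
              length(x$midline)))
  invisible(x)
}

## channels eligible for the symmetric average reference:
## every member of a mirror pair plus the midline set
reference_set <- function(montage) {
  unique(c(montage$mirror_pairs$left, montage$mirror_pairs$right,
           montage$midline))
}
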