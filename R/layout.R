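#' Probe layout: channel positions, probesets and ROI map
#'
#' Builds the optode/channel geometry used throughout the pipeline: three
#' probesets (left frontal, right frontal, parietal), each a 3 x 3 optode
#' grid with a fixed inter-optode distance, yielding 12 measurement
#' channels per probeset at the source-detector midpoints (36 channels,
#' 1-based ids). Five regions of interest cover the cognitive control
#' network: bilateral inferior frontal gyrus (IFG), bilateral dorsolateral
#' prefrontal cortex (DLPFC) and the somatosensory association cortex
#' (SAC).
#'
#' Positions are 2D scalp coordinates in millimetres. The within-probeset
#' geometry is exact (midpoints of a regular grid); the probeset offsets
#' are nominal placements consistent with frontal (F3/F4) and parietal
#' (Pz) montages. Spatial operations (channel interpolation, global-signal
#' reduction) only use pairwise distances, which vary smoothly with the
#' offsets.
#'
#' @param interoptode_distance Source-detector separation in mm (default 30).
#' @param roi_map Named list mapping ROI label to integer channel ids.
#'   Defaults to the study montage: lIFG = 6,7,9; lDLPFC = 10,11,12;
#'   rIFG = 18,19,21; rDLPFC = 20,23,24; SAC = 25,26,27,28,30,31,32,35,36.
#' @return An object of class `probe_layout`: list with `channels`
#'   (data.frame: channel, x_mm, y_mm, probeset), `roi_map`,
#'   `interoptode_distance`.
#' @export
probe_layout <- function(interoptode_distance = 30,
                         roi_map = list(
                           lIFG   = c(6L, 7L, 9L),
                           lDLPFC = c(10L, 11L, 12L),
                           rIFG   = c(18L, 19L, 21L),
                           rDLPFC = c(20L, 23L, 24L),
                           SAC    = c(25L, 26L, 27L, 28L, 30L, 31L, 32L, 35L, 36L)
                         )) {
  if (!is.numeric(interoptode_distance) || interoptode_distance <= 0) {
    stop("interoptode_distance must be > 0 mm")
  }
  d <- interoptode_distance
  # channel midpoints of a 3x3 optode grid, row-wise numbering:
  # horizontal pairs then vertical pairs, top row to bottom row
  rel <- matrix(c(
    d / 2, 0,       3 * d / 2, 0,
    0, d / 2,       d, d / 2,       2 * d, d / 2,
    d / 2, d,       3 * d / 2, d,
    0, 3 * d / 2,   d, 3 * d / 2,   2 * d, 3 * d / 2,
    d / 2, 2 * d,   3 * d / 2, 2 * d
  ), ncol = 2, byrow = TRUE)
  offsets <- list(
    `left frontal`  = c(-130, 60),
    `right frontal` = c(50, 60),
    parietal        = c(-40, -100)
  )
  channels <- do.call(rbind, lapply(seq_along(offsets), function(i) {
    data.frame(
      channel  = (i - 1L) * 12L + seq_len(12L),
      x_mm     = rel[, 1] + offsets[[i]][1],
      y_mm     = rel[, 2] + offsets[[i]][2],
      probeset = names(offsets)[i],
      stringsAsFactors = FALSE
    )
  }))
  layout <- structure(
    list(channels = channels, roi_map = roi_map,
         interoptode_distance = d),
    class = "probe_layout"
  )
  validate_probe_layout(layout)
  layout
}

#' Validate a probe layout
#'
#' Checks the structural invariants: ROI channel lists disjoint across
#' ROIs, every mapped channel present in the channel table, positive
#' inter-optode distance.
#'
#' @param layout A `probe_layout`.
#' @return The layout, invisibly; errors on violation.
#' @export
validate_probe_layout <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  ch <- layout$channels$channel
  if (anyDuplicated(ch)) stop("duplicate channel ids in layout")
  mapped <- unlist(layout$roi_map, use.names = FALSE)
  if (anyDuplicated(mapped)) {
    stop("ROI channel lists must be disjoint across ROIs")
  }
  missing <- setdiff(mapped, ch)
  if (length(missing)) {
    stop("ROI map references unknown channels: ",
         paste(missing, collapse = ", "))
  }
  if (layout$interoptode_distance <= 0) stop("interoptode_distance must be > 0")
  invisible(layout)
}

#' Pairwise channel distances (mm)
#'
#' @param layout A `probe_layout`.
#' @return Symmetric matrix of Euclidean scalp distances, dimnames =
#'   channel ids.
#' @export
channel_distances <- function(layout) {
  pos <- as.matrix(layout$channels[, c("x_mm", "y_mm")])
  dm <- as.matrix(stats::dist(pos))
  dimnames(dm) <- list(layout$channels$channel, layout$channels$channel)
  dm
}

#' @export
print.probe_layout <- function(x, ...) {
  cat("<probe_layout> ", nrow(x$channels), " channels, ",
      length(unique(x$channels$probeset)), " probesets, ",
      length(x$roi_map), " ROIs, d = ",
      x$interoptode_distance, " mm\n", sep = "")
  invisible(x)
}
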