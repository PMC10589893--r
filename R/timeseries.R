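#' Multi-channel fNIRS time series
#'
#' Container for a time x channel recording at one processing stage.
#' `data` is a named list of numeric matrices (time x channel), one per
#' band: wavelengths (e.g. "695", "830") for intensity / optical-density
#' stages, chromophores ("O2Hb", "HHb") for concentration stages, and a
#' single corrected-O2Hb band after correlation-based signal improvement.
#' The unit tag tracks stage provenance and converters enforce the legal
#' order intensity -> od -> conc -> z.
#'
#' @param data Named list of time x channel matrices (equal dims), or a
#'   single matrix (wrapped as one band).
#' @param fs Sampling rate in Hz (default 10).
#' @param unit One of "intensity", "od", "conc", "z".
#' @param channels Integer channel ids (default from column count).
#' @param bad Logical per-channel mask of flagged channels.
#' @param provenance Character vector of processing-stage notes, appended
#'   to by each stage.
#' @return Object of class `channel_ts`.
#' @export
channel_ts <- function(data, fs = 10, unit = c("intensity", "od", "conc", "z"),
                       channels = NULL, bad = NULL, provenance = character()) {
  unit <- match.arg(unit)
  if (is.matrix(data)) data <- list(value = data)
  if (!is.list(data) || !length(data)) stop("data must be a non-empty list of matrices")
  dims <- vapply(data, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all bands must share time x channel dimensions")
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  nc <- dims[2, 1]
  if (is.null(channels)) channels <- seq_len(nc)
  if (length(channels) != nc) stop("channels length must match column count")
  if (is.null(bad)) bad <- rep(FALSE, nc)
  structure(
    list(data = data, fs = fs, unit = unit,
         channels = as.integer(channels), bad = bad,
         provenance = provenance),
    class = "channel_ts"
  )
}

#' @export
print.channel_ts <- function(x, ...) {
  cat("<channel_ts> ", nrow(x$data[[1]]), " samples x ",
      length(x$channels), " channels @ ", x$fs, " Hz [", x$unit, "] bands: ",
      paste(names(x$data), collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_time <- function(ts) nrow(ts$data[[1]])
n_channels <- function(ts) length(ts$channels)

#' Time axis in seconds from recording start
#' @param ts A `channel_ts`.
#' @return Numeric vector, first sample at t = 0.
#' @export
time_axis <- function(ts) (seq_len(n_time(ts)) - 1) / ts$fs

assert_no_na <- function(ts, stage) {
  for (b in names(ts$data)) {
    if (anyNA(ts$data[[b]])) {
      stop("NaN/NA in band ", b, " after stage: ", stage)
    }
  }
  invisible(ts)
}

# legal unit order for stage transitions
.unit_order <- c(intensity = 1L, od = 2L, conc = 3L, z = 4L)

check_unit_transition <- function(from, to) {
  if (.unit_order[[to]] < .unit_order[[from]]) {
    stop("illegal unit transition ", from, " -> ", to)
  }
  invisible(TRUE)
}

#' Session events: trials, ratings and intervention log
#'
#' Ordered trial table for one training session plus per-trial subjective
#' ratings and the categorized log of therapeutic interventions given in
#' the talk phases between trials.
#'
#' @param trials data.frame with columns onset (s), duration (s),
#'   trial_type ("training"/"control"); optional rating columns
#'   burden, self_compassion, equanimity, effort.
#' @param interventions Optional data.frame (trial_index, phase, category).
#' @return Object of class `session_events`.
#' @export
session_events <- function(trials, interventions = NULL) {
  req <- c("onset", "duration", "trial_type")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials missing columns: ", paste(miss, collapse = ", "))
  trials <- trials[order(trials$onset), , drop = FALSE]
  rownames(trials) <- NULL
  if (any(diff(trials$onset) <= 0)) stop("trial onsets must be strictly increasing")
  ends <- trials$onset + trials$duration
  overlap <- which(trials$onset[-1] < ends[-length(ends)])
  if (length(overlap)) {
    stop("overlapping trials at indices ",
         paste(overlap, overlap + 1, sep = "-", collapse = ", "))
  }
  bad_type <- setdiff(unique(trials$trial_type), c("training", "control"))
  if (length(bad_type)) stop("unknown trial_type: ", paste(bad_type, collapse = ", "))
  trials$trial_index <- seq_len(nrow(trials))
  structure(list(trials = trials, interventions = interventions),
            class = "session_events")
}

#' @export
print.session_events <- function(x, ...) {
  tt <- table(x$trials$trial_type)
  cat("<session_events> ", nrow(x$trials), " trials (",
      paste(names(tt), tt, sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}
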