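#' Partition trials of each condition into session thirds
#'
#' Within each condition, trials are split by temporal order into three
#' contiguous groups as equal as possible, with remainders assigned to the
#' earlier thirds (20 trials -> 7/7/6; 40 -> 14/13/13).
#'
#' @param events A `session_events`.
#' @return Integer phase label (1, 2, 3) per trial, in trial order.
#' @export
split_thirds <- function(events) {
  stopifnot(inherits(events, "session_events"))
  trials <- events$trials
  phase <- integer(nrow(trials))
  for (cond in unique(trials$trial_type)) {
    idx <- which(trials$trial_type == cond)
    k <- length(idx)
    if (k < 3) stop("need >= 3 trials per condition (", cond, " has ", k, ")")
    base <- k %/% 3
    sizes <- base + as.integer(seq_len(3) <= k %% 3)
    phase[idx] <- rep(1:3, times = sizes)
  }
  phase
}

#' Event-related trial averages
#'
#' For each trial: subtract the mean of a pre-onset baseline window, then
#' average the signal over the analysis window, giving one scalar per
#' channel per trial. Defaults skip the hemodynamic rise (analysis window
#' 5-40 s post-onset) and use a -5-0 s baseline.
#'
#' @param ts `channel_ts` (typically unit "z" after cleaning).
#' @param events A `session_events`.
#' @param window Analysis window relative to onset (s), default `c(5, 40)`.
#' @param baseline Baseline window relative to onset (s), default `c(-5, 0)`.
#' @return Matrix trials x channels of baseline-corrected window means.
#' @export
epoch_average <- function(ts, events, window = c(5, 40), baseline = c(-5, 0)) {
  stopifnot(inherits(ts, "channel_ts"), inherits(events, "session_events"))
  x <- ts$data[[1]]
  tt <- time_axis(ts)
  trials <- events$trials
  out <- matrix(NA_real_, nrow(trials), ncol(x))
  colnames(out) <- ts$channels
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset[i]
    # half-open windows [start, end): the onset sample belongs to the
    # trial, not to the baseline
    wi <- which(tt >= on + window[1] & tt < on + window[2])
    bi <- which(tt >= on + baseline[1] & tt < on + baseline[2])
    if (!length(wi) || (on + window[2]) > max(tt) + 1 / ts$fs) {
      stop("analysis window outside recording for trial ", i)
    }
    base_mean <- if (length(bi)) colMeans(x[bi, , drop = FALSE]) else 0
    out[i, ] <- colMeans(x[wi, , drop = FALSE]) - base_mean
  }
  out
}

#' Average channel trial means into regions of interest
#'
#' Unweighted mean over each ROI's channels as defined in the layout's
#' ROI map. Channels flagged missing are dropped from their ROI with a
#' warning; an absent (unflagged) mapped channel is an error.
#'
#' @param trial_means Matrix trials x channels (colnames = channel ids).
#' @param layout A `probe_layout`.
#' @param missing_channels Channel ids to drop (flagged missing upstream).
#' @return Matrix trials x ROI.
#' @export
roi_average <- function(trial_means, layout, missing_channels = integer()) {
  ch <- as.integer(colnames(trial_means))
  out <- sapply(names(layout$roi_map), function(r) {
    want <- layout$roi_map[[r]]
    absent <- setdiff(want, ch)
    if (length(absent)) {
      stop("ROI ", r, " channels absent from data: ",
           paste(absent, collapse = ", "))
    }
    use <- setdiff(want, missing_channels)
    if (length(use) < length(want)) {
      warning("ROI ", r, ": averaging over ", length(use), "/",
              length(want), " channels (others missing)")
    }
    if (!length(use)) stop("ROI ", r, " has no usable channels")
    rowMeans(trial_means[, as.character(use), drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(layout$roi_map)))
  out
}

#' Training-minus-control contrast per session phase and ROI
#'
#' For each phase (session third) and ROI: mean over training trials
#' minus mean over control trials.
#'
#' @param roi_means Matrix trials x ROI from [roi_average()].
#' @param events A `session_events` (same trial order).
#' @param phase Integer phase labels from [split_thirds()].
#' @return data.frame: phase, roi, value (one row per phase x ROI).
#' @export
condition_contrast <- function(roi_means, events, phase = split_thirds(events)) {
  trials <- events$trials
  stopifnot(nrow(roi_means) == nrow(trials), length(phase) == nrow(trials))
  grid <- expand.grid(phase = 1:3, roi = colnames(roi_means),
                      stringsAsFactors = FALSE)
  grid$value <- mapply(function(p, r) {
    tr <- trials$trial_type == "training" & phase == p
    ct <- trials$trial_type == "control" & phase == p
    if (!any(tr) || !any(ct)) {
      stop("empty cell: phase ", p, ", condition ",
           if (!any(tr)) "training" else "control")
    }
    mean(roi_means[tr, r]) - mean(roi_means[ct, r])
  }, grid$phase, grid$roi)
  grid
}

#' Channel-wise effect-size map (one-sample Cohen's d)
#'
#' Per channel (and optionally per session): `d = mean(contrast) /
#' sd(contrast)` across subjects, the one-sample standardized difference
#' of the training-minus-control contrast against zero. Cells with zero
#' between-subject sd are flagged missing (NA).
#'
#' @param contrasts Matrix subjects x channels of per-subject contrasts.
#' @return Named numeric vector of d per channel (NA where sd = 0).
#' @export
effect_size_map <- function(contrasts) {
  if (nrow(contrasts) < 2) stop("need >= 2 subjects")
  apply(contrasts, 2, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(NA_real_)
    mean(v) / s
  })
}
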