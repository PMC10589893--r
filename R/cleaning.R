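#' Cleaning-chain configuration
#'
#' Parameters for the preprocessing chain. Defaults follow the study
#' pipeline: band-pass 0.01-0.1 Hz, spatial Gaussian global-signal kernel
#' sigma = 40 mm, automated bad-channel rules (variance outside
#' [0.01, 100] x median channel variance, or more than 75 % of samples
#' identical to their predecessor, i.e. a channel stuck for most of the
#' recording), TDDR convergence tolerance 1e-8.
#'
#' @param bandpass_low,bandpass_high Band edges in Hz.
#' @param global_sigma Gaussian kernel sd for global-signal estimation (mm).
#' @param interpolation_sigma Gaussian distance weighting sd for channel
#'   interpolation (mm).
#' @param var_floor,var_ceiling Variance bounds as multiples of the median
#'   channel variance.
#' @param saturation_frac Fraction of samples identical to their
#'   predecessor above which a channel counts as saturated/flat.
#' @param tddr_tolerance,tddr_max_iter TDDR robust-location convergence.
#' @return List of class `cleaning_config`.
#' @export
cleaning_config <- function(bandpass_low = 0.01, bandpass_high = 0.1,
                            global_sigma = 40, interpolation_sigma = 30,
                            var_floor = 0.01, var_ceiling = 100,
                            saturation_frac = 0.75,
                            tddr_tolerance = 1e-8, tddr_max_iter = 50) {
  if (!(bandpass_low > 0 && bandpass_low < bandpass_high)) {
    stop("need 0 < bandpass_low < bandpass_high")
  }
  if (global_sigma <= 0 || interpolation_sigma <= 0) stop("sigmas must be > 0")
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 global_sigma = global_sigma,
                 interpolation_sigma = interpolation_sigma,
                 var_floor = var_floor, var_ceiling = var_ceiling,
                 saturation_frac = saturation_frac,
                 tddr_tolerance = tddr_tolerance,
                 tddr_max_iter = tddr_max_iter),
            class = "cleaning_config")
}

#' Automated bad-channel detection
#'
#' Flags channels whose variance lies outside
#' `[var_floor, var_ceiling] x median channel variance` (in any band) or
#' whose fraction of samples identical to their predecessor exceeds
#' `saturation_frac`. Replaces the visual inspection used at acquisition
#' time with a reproducible rule.
#'
#' @param ts A `channel_ts` (>= 2 channels).
#' @param config A `cleaning_config`.
#' @return Logical per-channel mask.
#' @export
detect_bad_channels <- function(ts, config = cleaning_config()) {
  stopifnot(inherits(ts, "channel_ts"))
  nc <- n_channels(ts)
  if (nc < 2) stop("need >= 2 channels")
  bad <- rep(FALSE, nc)
  for (b in names(ts$data)) {
    x <- ts$data[[b]]
    v <- apply(x, 2, stats::var)
    med <- stats::median(v)
    if (med > 0) {
      bad <- bad | v < config$var_floor * med | v > config$var_ceiling * med
    }
    flat <- colMeans(diff(x) == 0) > config$saturation_frac
    bad <- bad | flat
  }
  if (all(bad)) stop("all channels flagged bad: unrecoverable recording")
  bad
}

#' Interpolate flagged channels from probeset neighbors
#'
#' Replaces each flagged channel by the Gaussian-distance-weighted average
#' of the good channels in the same probeset
#' (`w ~ exp(-d^2 / (2 sigma^2))`). Channels with no good neighbor in
#' their probeset stay flagged (marked missing) with a warning.
#'
#' @param ts A `channel_ts`.
#' @param bad Logical mask from [detect_bad_channels()].
#' @param layout A `probe_layout`.
#' @param sigma Weighting sd in mm.
#' @return `channel_ts` with interpolated channels and updated `bad` mask
#'   (cleared for repaired channels); attribute "interpolated" lists
#'   repaired channel ids.
#' @export
interpolate_channels <- function(ts, bad, layout,
                                 sigma = cleaning_config()$interpolation_sigma) {
  stopifnot(inherits(ts, "channel_ts"), inherits(layout, "probe_layout"))
  if (!any(bad)) {
    attr(ts, "interpolated") <- integer()
    return(ts)
  }
  dm <- channel_distances(layout)
  idx <- match(ts$channels, layout$channels$channel)
  if (anyNA(idx)) stop("channels missing from layout: configuration error")
  probeset <- layout$channels$probeset[idx]
  repaired <- integer()
  out <- ts$data
  for (j in which(bad)) {
    good <- which(!bad & probeset == probeset[j])
    if (!length(good)) {
      warning("channel ", ts$channels[j],
              " has no good neighbor in its probeset; marked missing")
      next
    }
    d <- dm[idx[j], idx[good]]
    w <- exp(-d^2 / (2 * sigma^2))
    w <- w / sum(w)
    for (b in names(out)) {
      out[[b]][, j] <- out[[b]][, good, drop = FALSE] %*% w
    }
    repaired <- c(repaired, j)
  }
  new_bad <- bad
  new_bad[repaired] <- FALSE
  res <- channel_ts(out, fs = ts$fs, unit = ts$unit, channels = ts$channels,
                    bad = new_bad,
                    provenance = c(ts$provenance,
                                   sprintf("interpolate_channels: %d repaired (sigma=%g mm)",
                                           length(repaired), sigma)))
  attr(res, "interpolated") <- ts$channels[repaired]
  res
}

# Zero-phase IIR filtering with odd-reflection edge padding. Plain
# forward-backward filtering leaves edge transients whose time constant
# (~1/cutoff) dwarfs the filter order, so the series is extended by an
# odd reflection about each endpoint (continuous in value and slope)
# long enough for the transient to die out, filtered both ways, and
# cropped.
filtfilt_pad <- function(bf, x, padlen) {
  n <- length(x)
  padlen <- min(n - 1, max(1L, round(padlen)))
  head_pad <- 2 * x[1] - x[seq(padlen + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  ext <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, ext)
  y <- rev(signal::filter(bf, rev(y)))
  y[seq(padlen + 1, padlen + n)]
}

#' Temporal Derivative Distribution Repair (TDDR)
#'
#' Motion-spike correction without tunable thresholds: the signal is split
#' at 0.5 Hz into low- and high-frequency parts; on the low-frequency part
#' the temporal derivative is robustly re-weighted (Tukey biweight,
#' `w = (1 - r'^2)^2` for `|r'| < 1` else 0, with
#' `r' = residual / (4.685 * 1.4826 * MAD)`), iterating the weighted
#' location estimate to convergence; the corrected derivative
#' `w * (derivative - location)` is integrated by cumulative sum, the
#' initial value restored, and the high-frequency part added back.
#'
#' @param x Numeric series (finite).
#' @param fs Sampling rate (Hz).
#' @param tol Convergence tolerance on the location estimate.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   and is flagged in the result.
#' @return List: `signal` (repaired series), `iterations`,
#'   `frac_downweighted` (share of derivative samples substantially
#'   down-weighted, w < 0.5), `converged`, `degenerate` (TRUE when the
#'   robust scale collapses relative to the derivative's spread, as in
#'   noise-free piecewise-constant signals -- the signal is then returned
#'   unrepaired).
#' @export
tddr <- function(x, fs, tol = 1e-8, max_iter = 50) {
  if (!all(is.finite(x))) stop("series must be finite")
  if (fs <= 0) stop("fs must be > 0")
  n <- length(x)
  if (n < 10) return(list(signal = x, iterations = 0L,
                          frac_downweighted = 0, converged = TRUE,
                          degenerate = FALSE))
  if (fs > 1) {
    bf <- signal::butter(3, 0.5 / (fs / 2), type = "low")
    low <- filtfilt_pad(bf, x, 5 * fs / 0.5)
    high <- x - low
  } else {
    low <- x
    high <- numeric(n)
  }
  dx <- diff(low)
  # degenerate-distribution guard: in (near-)noise-free piecewise-constant
  # signals the MAD scale collapses and the biweight would reject the true
  # hemodynamic transitions as outliers; leave such signals unrepaired
  sigma0 <- 1.4826 * stats::median(abs(dx - stats::median(dx)))
  if (sigma0 < 1e-6 * stats::sd(dx)) {
    return(list(signal = x, iterations = 0L, frac_downweighted = 0,
                converged = TRUE, degenerate = TRUE))
  }
  mu <- 0
  w <- rep(1, length(dx))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dev <- dx - mu
    sigma <- 1.4826 * stats::median(abs(dev - stats::median(dev)))
    if (sigma <= .Machine$double.eps) {
      # degenerate (e.g. constant signal): nothing to repair
      mu <- stats::median(dx)
      w <- rep(1, length(dx))
      converged <- TRUE
      break
    }
    r <- dev / (4.685 * sigma)
    w <- ifelse(abs(r) < 1, (1 - r^2)^2, 0)
    if (sum(w) <= 0) { converged <- TRUE; break }
    mu_new <- sum(w * dx) / sum(w)
    if (abs(mu_new - mu) < tol) { mu <- mu_new; converged <- TRUE; break }
    mu <- mu_new
    if (iter >= max_iter) break
  }
  corrected <- w * (dx - mu)
  low_fixed <- c(low[1], low[1] + cumsum(corrected))
  list(signal = low_fixed + high,
       iterations = iter,
       frac_downweighted = mean(w < 0.5),
       converged = converged, degenerate = FALSE)
}

#' Correlation-based signal improvement (CBSI)
#'
#' Combines O2Hb (sensitive) and HHb (artifact-resilient) into one
#' corrected signal, assuming the true hemodynamics are maximally
#' anti-correlated: with `alpha = sd(o2hb)/sd(hhb)` on the mean-centered
#' series, `corrected_o2hb = (o2hb - alpha * hhb) / 2` and
#' `corrected_hhb = -corrected_o2hb / alpha` (correlation exactly -1 by
#' construction). Downstream stages consume the corrected O2Hb only.
#'
#' @param o2hb,hhb Numeric series of equal length.
#' @param channel Channel id for error messages.
#' @return List: `o2hb`, `hhb` (corrected, mean-centered), `alpha`.
#' @export
cbsi <- function(o2hb, hhb, channel = NA) {
  if (length(o2hb) != length(hhb)) stop("series lengths differ")
  o <- o2hb - mean(o2hb)
  h <- hhb - mean(hhb)
  sh <- stats::sd(h)
  if (!is.finite(sh) || sh == 0) {
    stop("zero-variance HHb in channel ", channel)
  }
  alpha <- stats::sd(o) / sh
  x0 <- (o - alpha * h) / 2
  list(o2hb = x0, hhb = -x0 / alpha, alpha = alpha)
}

#' Zero-phase Butterworth band-pass
#'
#' 3rd-order Butterworth applied forward-backward (zero phase, squared
#' magnitude response). Removes slow drifts below `low` and noise above
#' `high`; DC is rejected.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges (Hz), `0 < low < high < fs/2`.
#' @param order Filter order (default 3).
#' @return Filtered series.
#' @export
bandpass <- function(x, fs, low = 0.01, high = 0.1, order = 3) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2")
  }
  min_len <- 3 * (2 * order + 1)
  if (length(x) <= min_len) {
    stop("series too short for filtering; need > ", min_len, " samples")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(filtfilt_pad(bf, x, 5 * fs / low))
}

#' Spatial global-signal reduction
#'
#' Estimates a per-channel global component as the Gaussian-kernel-
#' weighted average of the *other* channels (leave-one-out),
#' `g_i(t) = sum_{j != i} w_ij x_j(t)`, `w_ij ~ exp(-d_ij^2 / (2 sigma^2))`
#' normalized so each row sums to 1, and subtracts it. A component shared
#' additively by all channels is removed exactly; a signal localized to
#' one channel is untouched when its neighbors are far relative to sigma.
#' Excluding the channel itself keeps the estimate a spatial prediction
#' rather than partial self-subtraction.
#'
#' @param ts A `channel_ts` (>= 2 channels with positions in `layout`).
#' @param layout A `probe_layout`.
#' @param sigma Kernel sd in mm (default 40).
#' @return `channel_ts` with the global component removed per band.
#' @export
global_signal_reduction <- function(ts, layout, sigma = 40) {
  stopifnot(inherits(ts, "channel_ts"), inherits(layout, "probe_layout"))
  if (n_channels(ts) < 2) stop("need >= 2 channels")
  idx <- match(ts$channels, layout$channels$channel)
  if (anyNA(idx)) stop("channel positions missing: configuration error")
  dm <- channel_distances(layout)[idx, idx, drop = FALSE]
  W <- exp(-dm^2 / (2 * sigma^2))
  diag(W) <- 0
  W <- W / rowSums(W)
  out <- lapply(ts$data, function(x) x - x %*% t(W))
  channel_ts(out, fs = ts$fs, unit = ts$unit, channels = ts$channels,
             bad = ts$bad,
             provenance = c(ts$provenance,
                            sprintf("global_signal_reduction: sigma=%g mm", sigma)))
}

#' Per-channel z-transform
#'
#' Standardizes each channel over the session: `(x - mean) / sd`, sample
#' sd (n-1 denominator). Makes sessions comparable across subjects.
#'
#' @param ts A `channel_ts`.
#' @return `channel_ts` with unit "z"; every channel has mean 0, sd 1.
#' @export
zscore_channels <- function(ts) {
  stopifnot(inherits(ts, "channel_ts"))
  check_unit_transition(ts$unit, "z")
  out <- lapply(ts$data, function(x) {
    s <- apply(x, 2, stats::sd)
    zv <- which(!is.finite(s) | s == 0)
    if (length(zv)) {
      stop("zero variance in channel ", ts$channels[zv[1]])
    }
    scale(x, center = TRUE, scale = s)[, , drop = FALSE]
  })
  channel_ts(out, fs = ts$fs, unit = "z", channels = ts$channels,
             bad = ts$bad, provenance = c(ts$provenance, "zscore"))
}

#' Run the full preprocessing chain
#'
#' Applies, in order: bad-channel detection + interpolation, TDDR per
#' channel, CBSI (collapsing O2Hb/HHb to corrected O2Hb), band-pass,
#' a second detection + interpolation pass (for artifacts introduced by
#' correction), spatial global-signal reduction, and per-channel
#' z-transform. Deterministic given inputs and config.
#'
#' @param ts `channel_ts` with unit "conc" and bands O2Hb, HHb.
#' @param layout A `probe_layout`.
#' @param config A `cleaning_config`.
#' @return List: `ts` (`channel_ts`, unit "z", single band `O2Hb_corr`),
#'   `report` (per-stage interpolated channels, TDDR iteration counts and
#'   down-weighting fractions, filter metadata).
#' @export
run_cleaning_chain <- function(ts, layout, config = cleaning_config()) {
  stopifnot(inherits(ts, "channel_ts"))
  if (ts$unit != "conc") stop("cleaning chain expects unit 'conc'")
  report <- list()

  bad1 <- detect_bad_channels(ts, config)
  ts1 <- interpolate_channels(ts, bad1, layout, config$interpolation_sigma)
  report$interpolated_pass1 <- attr(ts1, "interpolated")

  tddr_iter <- matrix(0L, nrow = 2, ncol = n_channels(ts1),
                      dimnames = list(names(ts1$data), NULL))
  tddr_frac <- tddr_iter * 0
  nonconv <- character()
  for (b in names(ts1$data)) {
    for (j in seq_len(n_channels(ts1))) {
      r <- tddr(ts1$data[[b]][, j], ts1$fs,
                tol = config$tddr_tolerance, max_iter = config$tddr_max_iter)
      ts1$data[[b]][, j] <- r$signal
      tddr_iter[b, j] <- r$iterations
      tddr_frac[b, j] <- r$frac_downweighted
      if (!r$converged) {
        nonconv <- c(nonconv, paste0(b, ":", ts1$channels[j]))
      }
    }
  }
  report$tddr_iterations <- tddr_iter
  report$tddr_frac_downweighted <- tddr_frac
  report$tddr_nonconverged <- nonconv

  nco <- n_channels(ts1)
  corr <- matrix(0, n_time(ts1), nco)
  alphas <- numeric(nco)
  for (j in seq_len(nco)) {
    cb <- cbsi(ts1$data$O2Hb[, j], ts1$data$HHb[, j], channel = ts1$channels[j])
    corr[, j] <- cb$o2hb
    alphas[j] <- cb$alpha
  }
  report$cbsi_alpha <- alphas
  ts2 <- channel_ts(list(O2Hb_corr = corr), fs = ts1$fs, unit = "conc",
                    channels = ts1$channels, bad = ts1$bad,
                    provenance = c(ts1$provenance, "cbsi"))

  ts2$data$O2Hb_corr <- apply(ts2$data$O2Hb_corr, 2, bandpass, fs = ts2$fs,
                              low = config$bandpass_low,
                              high = config$bandpass_high)
  report$filter <- sprintf("butterworth order 3 zero-phase [%g, %g] Hz",
                           config$bandpass_low, config$bandpass_high)

  bad2 <- detect_bad_channels(ts2, config)
  ts3 <- interpolate_channels(ts2, bad2, layout, config$interpolation_sigma)
  report$interpolated_pass2 <- attr(ts3, "interpolated")

  ts4 <- global_signal_reduction(ts3, layout, config$global_sigma)
  ts5 <- zscore_channels(ts4)
  assert_no_na(ts5, "cleaning chain")
  list(ts = ts5, report = report)
}
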