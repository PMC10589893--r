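#' Modified Beer-Lambert law parameters
#'
#' Bundles the molar extinction coefficients, differential pathlength
#' factors (DPF) and source-detector distance used to map optical-density
#' changes at two wavelengths onto chromophore concentration changes.
#'
#' The default extinction table is interpolated at 695 and 830 nm from the
#' standard compendium of hemoglobin spectra distributed with most NIRS
#' software (units 1/(mM*cm)): at 695 nm O2Hb 0.283, HHb 1.923; at 830 nm
#' O2Hb 0.974, HHb 0.693. DPF defaults to 6.0 at both wavelengths and the
#' distance to 3 cm. Downstream z-scoring makes results invariant to the
#' overall positive scale of these constants but not to the mixing matrix,
#' so the values used are recorded in the series provenance.
#'
#' @param extinction 2 x 2 matrix, rows = wavelengths, cols = chromophores
#'   c("O2Hb", "HHb"), units 1/(mM*cm).
#' @param dpf Differential pathlength factor per wavelength (dimensionless).
#' @param distance Source-detector distance in cm (default 3).
#' @return Object of class `mbll_params`.
#' @export
mbll_params <- function(extinction = matrix(c(0.283, 1.923,
                                              0.974, 0.693),
                                            nrow = 2, byrow = TRUE,
                                            dimnames = list(c("695", "830"),
                                                            c("O2Hb", "HHb"))),
                        dpf = c(6.0, 6.0), distance = 3.0) {
  stopifnot(is.matrix(extinction), all(dim(extinction) == c(2, 2)))
  if (any(dpf <= 0)) stop("dpf must be > 0")
  if (distance <= 0) stop("distance must be > 0")
  A <- diag(dpf * distance) %*% extinction  # effective mixing matrix
  if (!is.finite(rcond(A)) || rcond(A) < 1e-12) {
    stop("extinction/DPF/distance give a singular effective matrix")
  }
  structure(list(extinction = extinction, dpf = dpf, distance = distance,
                 mixing = A),
            class = "mbll_params")
}

#' Optical density changes from raw intensities
#'
#' Computes per channel and wavelength the optical-density change
#' `dOD(t) = -ln(I(t) / I0)` with `I0` the mean intensity over a baseline
#' window. Natural log is used throughout. The transform is invariant to
#' rescaling all intensities of a channel by a positive constant.
#'
#' @param ts `channel_ts` with unit "intensity"; bands are wavelengths.
#' @param baseline_window Numeric length-2 window (s) defining I0
#'   (default first 30 s).
#' @return `channel_ts` with unit "od"; baseline-window mean of each
#'   channel is ~0 by construction.
#' @export
od_from_intensity <- function(ts, baseline_window = c(0, 30)) {
  stopifnot(inherits(ts, "channel_ts"))
  if (ts$unit != "intensity") stop("input unit must be 'intensity'")
  tt <- time_axis(ts)
  idx <- which(tt >= baseline_window[1] & tt <= baseline_window[2])
  if (!length(idx)) stop("baseline window is empty")
  od <- lapply(names(ts$data), function(b) {
    x <- ts$data[[b]]
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-positive intensity in band %s, channel %d, sample %d",
                   b, ts$channels[bad[1, 2]], bad[1, 1]))
    }
    i0 <- colMeans(x[idx, , drop = FALSE])
    -log(sweep(x, 2, i0, "/"))
  })
  names(od) <- names(ts$data)
  channel_ts(od, fs = ts$fs, unit = "od", channels = ts$channels,
             bad = ts$bad,
             provenance = c(ts$provenance,
                            sprintf("od_from_intensity: baseline [%g, %g] s, natural log",
                                    baseline_window[1], baseline_window[2])))
}

#' Chromophore concentration changes via the modified Beer-Lambert law
#'
#' Inverts the linear mixing `dOD_lambda = d * DPF_lambda *
#' sum_c eps_{lambda,c} dC_c` per channel and time point, giving
#' concentration changes for O2Hb and HHb (mM, given the default units).
#'
#' @param ts `channel_ts` with unit "od" and two wavelength bands.
#' @param params An `mbll_params` object.
#' @return `channel_ts` with unit "conc" and bands "O2Hb", "HHb".
#' @export
mbll <- function(ts, params = mbll_params()) {
  stopifnot(inherits(ts, "channel_ts"), inherits(params, "mbll_params"))
  if (ts$unit != "od") stop("input unit must be 'od'")
  if (length(ts$data) != 2) stop("two wavelength bands required")
  Ainv <- solve(params$mixing)
  n <- n_time(ts); nc <- n_channels(ts)
  o2hb <- matrix(0, n, nc); hhb <- matrix(0, n, nc)
  for (j in seq_len(nc)) {
    od <- cbind(ts$data[[1]][, j], ts$data[[2]][, j])
    conc <- od %*% t(Ainv)
    o2hb[, j] <- conc[, 1]; hhb[, j] <- conc[, 2]
  }
  channel_ts(list(O2Hb = o2hb, HHb = hhb), fs = ts$fs, unit = "conc",
             channels = ts$channels, bad = ts$bad,
             provenance = c(ts$provenance,
                            sprintf("mbll: dpf=[%g,%g], d=%g cm, ext=[%s]",
                                    params$dpf[1], params$dpf[2], params$distance,
                                    paste(signif(params$extinction, 4), collapse = ","))))
}

#' Forward optics model: concentrations to raw intensities
#'
#' Inverse of [od_from_intensity()] + [mbll()]; used by the simulator to
#' emit raw dual-wavelength recordings and by round-trip tests.
#'
#' @param ts `channel_ts` with unit "conc" (bands O2Hb, HHb).
#' @param params An `mbll_params`.
#' @param i0 Baseline intensity per wavelength (arbitrary units).
#' @return `channel_ts` with unit "intensity", bands named by wavelength.
#' @export
conc_to_intensity <- function(ts, params = mbll_params(), i0 = c(1, 1)) {
  stopifnot(inherits(ts, "channel_ts"), ts$unit == "conc")
  A <- params$mixing
  nc <- n_channels(ts)
  out <- lapply(1:2, function(w) {
    od <- ts$data[["O2Hb"]] * A[w, 1] + ts$data[["HHb"]] * A[w, 2]
    i0[w] * exp(-od)
  })
  names(out) <- rownames(params$extinction)
  channel_ts(out, fs = ts$fs, unit = "intensity", channels = ts$channels)
}

#' Canonical double-gamma hemodynamic response function
#'
#' `hrf(t)` is the difference of two gamma densities (shape = delay + 1,
#' rate = 1) normalized to peak amplitude 1: a positive peak near
#' `peak_delay` seconds followed by an undershoot. `hrf(0) = 0`.
#'
#' @param t Time in seconds (vector, t >= 0).
#' @param peak_delay Peak latency (s, default 6).
#' @param undershoot_delay Undershoot latency (s, default 16).
#' @param ratio Undershoot-to-peak amplitude ratio before normalization
#'   (default 1/6).
#' @return Numeric vector of amplitudes (a.u., peak = 1).
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          ratio = 1 / 6) {
  if (any(t < 0)) stop("t must be >= 0")
  if (peak_delay <= 0 || undershoot_delay <= 0 || ratio < 0) {
    stop("shape parameters must be positive")
  }
  h <- stats::dgamma(t, shape = peak_delay + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay + 1, rate = 1)
  grid <- seq(0, undershoot_delay + 16, by = 0.01)
  hg <- stats::dgamma(grid, shape = peak_delay + 1, rate = 1) -
    ratio * stats::dgamma(grid, shape = undershoot_delay + 1, rate = 1)
  h / max(hg)
}

#' Convolve a stimulus time course with the canonical HRF
#'
#' @param stim Stimulus vector sampled at `fs` (e.g. a trial boxcar).
#' @param fs Sampling rate (Hz).
#' @param ... Passed to [canonical_hrf()].
#' @return Vector of the same length as `stim`, scaled so that a
#'   sustained unit boxcar plateaus at ~1 (kernel normalized by its sum x
#'   dt at plateau).
#' @export
hrf_convolve <- function(stim, fs, ...) {
  t_kernel <- seq(0, 32, by = 1 / fs)
  k <- canonical_hrf(t_kernel, ...)
  k <- k / sum(k)  # unit-gain at DC: sustained unit input -> plateau 1
  out <- stats::filter(stim, k, method = "convolution", sides = 1)
  out[is.na(out)] <- 0
  as.numeric(out)
}
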