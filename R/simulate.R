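#' Simulation configuration for the synthetic study
#'
#' Defaults emulate the study conditions: 42 subjects, 8 sessions of
#' 20 training + 20 control trials of 40 s, block-randomized per 10
#' trials, inter-trial talk gaps uniform on 20-60 s, 10 Hz sampling.
#' Signal-level effect amplitudes (concentration units before
#' z-scoring) are largest in prefrontal ROIs and decline linearly over
#' sessions in the bilateral DLPFC; contrast-level parameters (z-units)
#' are calibrated so the constant-term effect sizes fall in the
#' 0.2-0.5 partial-eta-squared range at n = 42. Behavioral defaults:
#' ratings on a bounded 0-10 continuous scale with linear session/phase
#' trends (burden/effort down, self-compassion/equanimity up, a
#' quadratic phase component for effort); intervention draws use the
#' observed phase shares (39.2/42.4/18.3 %), session shares declining
#' from 14 % to 11.4 %, and the 13-label category shares; questionnaire
#' trajectories follow the cross-over (treatment-first improves t1->t2
#' then holds, TAU-first improves t2->t3) with configured paired
#' t1->t3 effect-size targets.
#'
#' @param ... Named overrides of any default listed above (see the
#'   function body for the full set).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_subjects = 42L, n_sessions = 8L,
    n_trials_per_condition = 20L, block = 10L,
    trial_duration = 40, talk_gap = c(20, 60), fs = 10,
    # signal-level forward model (concentration units, pre-z)
    effect_session1 = c(lIFG = 0.8, lDLPFC = 1.0, rIFG = 0.8,
                        rDLPFC = 1.0, SAC = 0.3),
    effect_slope = c(lIFG = 0, lDLPFC = -0.06, rIFG = 0,
                     rDLPFC = -0.06, SAC = 0),
    effect_background = 0.15,
    amp_subject_sd = 0.2,
    noise = list(white_sd = 0.3, drift_sd = 0.3,
                 cardiac_amp = 0.2, cardiac_hz = 1.1,
                 resp_amp = 0.2, resp_hz = 0.25,
                 mayer_amp = 0.25, mayer_hz = 0.1,
                 spike_rate_per_min = 0.5, spike_amp = 2,
                 global_sd = 0.5),
    hhb_ratio = 3, hhb_noise_sd = 0.1,
    # contrast-level generator (z-units)
    contrast_session1 = c(lIFG = 0.30, lDLPFC = 0.35, rIFG = 0.30,
                          rDLPFC = 0.35, SAC = 0.08),
    contrast_slope = c(lIFG = 0, lDLPFC = -0.035, rIFG = 0,
                       rDLPFC = -0.035, SAC = 0),
    contrast_subject_sd = 0.25, contrast_roi_sd = 0.25,
    contrast_resid_sd = 0.45,
    # per-trial subjective ratings, bounded 0-10 continuous
    rating_scale = c(0, 10),
    ratings = list(
      burden = list(base = 4, gap = 2, sess = c(training = -0.15, control = -0.02),
                    phase = c(training = -0.5, control = -0.1),
                    quad = c(training = 0, control = 0)),
      self_compassion = list(base = 5, gap = -1,
                             sess = c(training = 0.12, control = 0.02),
                             phase = c(training = 0.45, control = 0.05),
                             quad = c(training = -0.12, control = 0)),
      equanimity = list(base = 5, gap = -1.5,
                        sess = c(training = 0.10, control = 0.02),
                        phase = c(training = 0.45, control = 0.05),
                        quad = c(training = 0, control = 0)),
      effort = list(base = 5.5, gap = 2,
                    sess = c(training = -0.16, control = -0.02),
                    phase = c(training = -0.2, control = 0),
                    quad = c(training = -0.25, control = 0))
    ),
    rating_subject_sd = 0.7, rating_noise_sd = 0.8,
    rating_gap_subject_sd = 1.5,
    # intervention log generator
    intervention_session_weights = c(14, 13.8, 12.5, 12.4, 12.5, 11.8,
                                     11.5, 11.4),
    intervention_phase_weights = c(39.2, 42.4, 18.3),
    intervention_category_weights = c(
      "cognitive reframing / reappraisal" = 22.2,
      "validation" = 15.6,
      "distancing and equanimity" = 14.4,
      "attention regulation" = 13.6,
      "self-compassion" = 13.4,
      "acceptance" = 10.6,
      "metaphor" = 2.5,
      "motivational interviewing" = 2.0,
      "self-instruction" = 1.7,
      "control of body function" = 1.3,
      "socratic questioning" = 1.1,
      "chaining" = 0.9,
      "pretending to" = 0.7),
    interventions_per_session = 18,
    # cross-over questionnaire trajectories
    questionnaire_n = 41L,
    questionnaires = list(
      BDI = list(baseline = 26.51, baseline_sd = 7.78, occasion_sd = 3.5,
                 d13 = -1.47),
      SWE = list(baseline = 24, baseline_sd = 6, occasion_sd = 2.5,
                 d13 = 0.88),
      SCS = list(baseline = 2.6, baseline_sd = 0.55, occasion_sd = 0.25,
                 d13 = 1.75),
      SRQ = list(baseline = 3.8, baseline_sd = 0.9, occasion_sd = 0.45,
                 d13 = -1.85)
    ),
    # rating ~ oxygenation mixed-model generator (training trials)
    lmm = list(beta0 = 6, beta_session = -0.12, beta_phase = -0.35,
               beta_lag = 0.3, beta_wp = -0.4, beta_bp = 0.4,
               bp_sd = 0.4, wp_sd = 0.5,
               subject_sd = 0.8, resid_sd = 0.8)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  w <- cfg$intervention_phase_weights
  if (any(w < 0)) stop("weights must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Derive a deterministic sub-seed
#'
#' Maps a master seed plus subject/session/salt indices to a stable
#' integer below 2^31, so every generator in a cohort gets its own
#' reproducible stream.
#'
#' @param seed Master seed (integer).
#' @param subject,session,salt Non-negative stream indices.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, subject = 0, session = 0, salt = 0) {
  as.integer((as.numeric(seed) * 7919 + subject * 1009 +
                session * 131 + salt * 17 + 1) %% 2147483629)
}

#' Simulate the block-randomized trial sequence of one session
#'
#' Each consecutive block of `block` trials contains exactly
#' `block/2` training and `block/2` control trials in random order;
#' onsets accumulate a uniform talk gap plus the trial duration.
#'
#' @param n_trials Total trials (default 40), divisible by `block`.
#' @param block Block length (default 10, even).
#' @param trial_duration Trial length in s (default 40).
#' @param talk_gap Uniform range (s) of the pre-trial talk gap.
#' @param seed RNG seed.
#' @return A `session_events` with `n_trials` rows.
#' @export
simulate_design <- function(n_trials = 40, block = 10, trial_duration = 40,
                            talk_gap = c(20, 60), seed = 1) {
  if (n_trials %% block != 0) stop("n_trials must be divisible by block")
  if (block %% 2 != 0) stop("block must be even")
  set.seed(seed)
  cond <- unlist(lapply(seq_len(n_trials / block), function(b) {
    sample(rep(c("training", "control"), each = block / 2))
  }))
  gaps <- stats::runif(n_trials, talk_gap[1], talk_gap[2])
  onsets <- cumsum(gaps + trial_duration) - trial_duration
  session_events(data.frame(onset = onsets,
                            duration = trial_duration,
                            trial_type = cond,
                            stringsAsFactors = FALSE))
}

#' Simulate one session's channel-level concentration signals
#'
#' Forward model per channel: ROI effect amplitude (declining linearly
#' over sessions in the DLPFC by default; channels outside named ROIs get
#' a small background amplitude) times the HRF-convolved
#' training-trial boxcar, plus sinusoidal physiological components
#' (cardiac, respiratory, Mayer waves) with random phases, a random-walk
#' drift, Poisson-counted motion artifacts (abrupt persistent baseline
#' shifts, the artifact class TDDR repairs), a global component
#' shared by all channels, and white noise. HHb is generated
#' anti-correlated as `-O2Hb/hhb_ratio` plus independent noise.
#'
#' @param events A `session_events`.
#' @param layout A `probe_layout`.
#' @param config A `sim_config`.
#' @param subject,session Indices (session scales the DLPFC decline).
#' @param seed RNG seed.
#' @param noise_scale Multiplier on every noise amplitude (0 = noiseless).
#' @return List: `ts` (`channel_ts`, unit "conc", bands O2Hb/HHb),
#'   `truth` (per-channel effect amplitude, regressor, spike samples).
#' @export
simulate_session_signal <- function(events, layout, config = sim_config(),
                                    subject = 1, session = 1, seed = 1,
                                    noise_scale = 1) {
  set.seed(seed)
  fs <- config$fs
  trials <- events$trials
  dur <- max(trials$onset + trials$duration) + 20
  nt <- ceiling(dur * fs)
  tt <- (seq_len(nt) - 1) / fs

  stim <- numeric(nt)
  for (i in which(trials$trial_type == "training")) {
    stim[tt >= trials$onset[i] & tt < trials$onset[i] + trials$duration[i]] <- 1
  }
  regressor <- hrf_convolve(stim, fs)

  nc <- nrow(layout$channels)
  chan_roi <- rep(NA_character_, nc)
  for (r in names(layout$roi_map)) {
    chan_roi[match(layout$roi_map[[r]], layout$channels$channel)] <- r
  }
  amp <- numeric(nc)
  for (j in seq_len(nc)) {
    base <- if (!is.na(chan_roi[j])) {
      config$effect_session1[[chan_roi[j]]] +
        config$effect_slope[[chan_roi[j]]] * (session - 1)
    } else {
      config$effect_background  # cortex outside named ROIs still responds
    }
    amp[j] <- max(0, base + stats::rnorm(1, 0, config$amp_subject_sd *
                                             noise_scale))
  }

  ns <- config$noise
  g <- if (ns$global_sd > 0 && noise_scale > 0) {
    raw <- stats::rnorm(nt)
    bf <- signal::butter(2, 0.4 / (fs / 2), type = "low")
    sm <- filtfilt_pad(bf, raw, 5 * fs / 0.4)
    sm / stats::sd(sm) * ns$global_sd * noise_scale
  } else numeric(nt)

  o2hb <- matrix(0, nt, nc)
  hhb <- matrix(0, nt, nc)
  spike_n <- integer(nc)
  for (j in seq_len(nc)) {
    x <- amp[j] * regressor + g
    if (noise_scale > 0) {
      phase <- stats::runif(3, 0, 2 * pi)
      x <- x +
        noise_scale * ns$cardiac_amp * sin(2 * pi * ns$cardiac_hz * tt + phase[1]) +
        noise_scale * ns$resp_amp * sin(2 * pi * ns$resp_hz * tt + phase[2]) +
        noise_scale * ns$mayer_amp * sin(2 * pi * ns$mayer_hz * tt + phase[3])
      drift <- cumsum(stats::rnorm(nt)) / sqrt(nt)
      x <- x + noise_scale * ns$drift_sd * drift
      n_spikes <- stats::rpois(1, ns$spike_rate_per_min * dur / 60)
      spike_n[j] <- n_spikes
      if (n_spikes > 0) {
        # motion artifacts: abrupt persistent baseline shifts
        at <- sample.int(nt, n_spikes)
        for (a in at) {
          x[a:nt] <- x[a:nt] + sample(c(-1, 1), 1) * noise_scale * ns$spike_amp
        }
      }
      x <- x + stats::rnorm(nt, 0, ns$white_sd * noise_scale)
    }
    o2hb[, j] <- x
    hhb[, j] <- -x / config$hhb_ratio +
      stats::rnorm(nt, 0, config$hhb_noise_sd * noise_scale)
  }
  ts <- channel_ts(list(O2Hb = o2hb, HHb = hhb), fs = fs, unit = "conc",
                   channels = layout$channels$channel,
                   provenance = sprintf("simulated subject %d session %d seed %d",
                                        subject, session, seed))
  list(ts = ts,
       truth = list(amplitude = stats::setNames(amp, layout$channels$channel),
                    roi = chan_roi, regressor = regressor,
                    n_spikes = spike_n))
}

#' Simulate per-trial subjective ratings for one session
#'
#' Cell-mean model per rating: base + condition gap (plus a stable
#' per-subject gap deviation, the source of between-subject variability
#' in the condition contrast) + linear session and phase trends
#' (condition-specific) + centered quadratic phase term + session-level
#' subject intercept + Gaussian noise, truncated to the bounded rating
#' scale. With `noise_scale = 0` and no gap offsets the cell means equal
#' the configured model exactly.
#'
#' @param events A `session_events`.
#' @param config A `sim_config`.
#' @param subject,session Indices.
#' @param seed RNG seed.
#' @param noise_scale Multiplier on subject/trial noise.
#' @param gap_offset Named numeric (one entry per rating): this subject's
#'   deviation from the configured condition gap, held constant across
#'   the subject's sessions (drawn by [simulate_cohort()]).
#' @return data.frame: trial_index, trial_type, phase, and one column per
#'   rating.
#' @export
simulate_behavior <- function(events, config = sim_config(), subject = 1,
                              session = 1, seed = 1, noise_scale = 1,
                              gap_offset = NULL) {
  set.seed(seed)
  trials <- events$trials
  phase <- split_thirds(events)
  out <- data.frame(trial_index = trials$trial_index,
                    trial_type = trials$trial_type, phase = phase)
  for (rn in names(config$ratings)) {
    rc <- config$ratings[[rn]]
    gap <- rc$gap + if (!is.null(gap_offset)) gap_offset[[rn]] else 0
    b_subj <- stats::rnorm(1, 0, config$rating_subject_sd * noise_scale)
    mu <- rc$base + (trials$trial_type == "training") * gap +
      rc$sess[trials$trial_type] * (session - 1) +
      rc$phase[trials$trial_type] * (phase - 2) +
      rc$quad[trials$trial_type] * ((phase - 2)^2 - 2 / 3)
    v <- mu + b_subj + stats::rnorm(nrow(trials), 0,
                                    config$rating_noise_sd * noise_scale)
    out[[rn]] <- pmin(config$rating_scale[2], pmax(config$rating_scale[1], v))
  }
  out
}

#' Draw therapeutic-intervention events
#'
#' Each intervention event gets a session, a session phase and a category
#' drawn independently from the configured weight vectors (session shares
#' declining across sessions, phase shares concentrated in the first two
#' thirds, 13 category labels).
#'
#' @param n Number of events.
#' @param config A `sim_config`.
#' @param seed RNG seed.
#' @return data.frame: session, phase, category.
#' @export
simulate_interventions <- function(n, config = sim_config(), seed = 1) {
  set.seed(seed)
  sw <- config$intervention_session_weights
  pw <- config$intervention_phase_weights
  cw <- config$intervention_category_weights
  norm <- function(x) {
    if (any(x < 0)) stop("weights must be >= 0")
    x / sum(x)
  }
  data.frame(
    session = sample(seq_along(sw), n, TRUE, norm(sw)),
    phase = sample(seq_along(pw), n, TRUE, norm(pw)),
    category = sample(names(cw), n, TRUE, norm(cw)),
    stringsAsFactors = FALSE
  )
}

#' Simulate cross-over questionnaire trajectories
#'
#' Two groups over three timepoints: the treatment-first group improves
#' from t1 to t2 and then holds; the TAU-first group holds from t1 to t2
#' and improves from t2 to t3 (delayed u-shaped group difference). Each
#' scale's total change is `d13 * sqrt(2) * occasion_sd`, so the paired
#' t1->t3 effect size across all subjects targets the configured `d13`.
#'
#' @param config A `sim_config`.
#' @param seed RNG seed.
#' @param noise_scale Multiplier on subject/occasion noise.
#' @return List: `data` (long data.frame: subject, group, time, one
#'   column per scale), `truth` (group x time cell means per scale).
#' @export
simulate_questionnaires <- function(config = sim_config(), seed = 1,
                                    noise_scale = 1) {
  set.seed(seed)
  n <- config$questionnaire_n
  group <- rep(c("treatment_first", "tau_first"), length.out = n)
  long <- expand.grid(subject = seq_len(n), time = 1:3)
  long$group <- group[long$subject]
  truth <- list()
  for (qn in names(config$questionnaires)) {
    qc <- config$questionnaires[[qn]]
    tau <- sqrt(max(0, qc$baseline_sd^2 - qc$occasion_sd^2))
    delta <- qc$d13 * sqrt(2) * qc$occasion_sd
    traj <- rbind(treatment_first = qc$baseline + delta * c(0, 1, 1),
                  tau_first = qc$baseline + delta * c(0, 0, 1))
    truth[[qn]] <- traj
    b <- stats::rnorm(n, 0, tau * noise_scale)
    mu <- traj[cbind(match(long$group, rownames(traj)), long$time)]
    long[[qn]] <- mu + b[long$subject] +
      stats::rnorm(nrow(long), 0, qc$occasion_sd * noise_scale)
  }
  list(data = long, truth = truth)
}

#' Simulate a contrast-level cohort with known ground truth
#'
#' Draws training-minus-control contrast records (z-units) directly from
#' the configured cell-mean model: per subject x session x phase x ROI,
#' `value = session-slope cell mean + subject intercept (shared and
#' ROI-specific components) + noise`. This is
#' the statistical structure the inference layer assumes; the signal-level
#' forward model (see [simulate_session_signal()]) produces the same
#' records through the full preprocessing chain.
#'
#' @param config A `sim_config`.
#' @param seed RNG seed.
#' @param n_subjects Override of `config$n_subjects`.
#' @param effect_scale Multiplier on all ROI means (0 = null cohort).
#' @return List: `contrasts` (tidy data.frame subject, session, phase,
#'   roi, value), `truth` (cell-mean array and parameters).
#' @export
simulate_contrast_cohort <- function(config = sim_config(), seed = 1,
                                     n_subjects = config$n_subjects,
                                     effect_scale = 1) {
  set.seed(seed)
  rois <- names(config$contrast_session1)
  grid <- expand.grid(subject = seq_len(n_subjects),
                      session = seq_len(config$n_sessions),
                      phase = 1:3, roi = rois,
                      stringsAsFactors = FALSE)
  mu <- effect_scale * (config$contrast_session1[grid$roi] +
                          config$contrast_slope[grid$roi] * (grid$session - 1))
  b <- stats::rnorm(n_subjects, 0, config$contrast_subject_sd)
  b_roi <- matrix(stats::rnorm(n_subjects * length(rois), 0,
                               config$contrast_roi_sd),
                  n_subjects, length(rois), dimnames = list(NULL, rois))
  grid$value <- mu + b[grid$subject] +
    b_roi[cbind(grid$subject, match(grid$roi, rois))] +
    stats::rnorm(nrow(grid), 0, config$contrast_resid_sd)
  list(contrasts = grid,
       truth = list(mu = mu, subject_intercepts = b,
                    session1 = effect_scale * config$contrast_session1,
                    slope = effect_scale * config$contrast_slope))
}

#' Simulate training-trial ratings from the mixed-model process
#'
#' Generates per-trial records whose data-generating process is exactly
#' the lagged mixed model fitted by [fit_lmm()]: known fixed coefficients
#' for session, phase, the lagged rating, and within/between-person
#' oxygenation (WP/BP, defaults with opposite signs), a random intercept
#' per subject, and Gaussian residuals. First trials per session carry no
#' lag term (they are dropped in fitting).
#'
#' @param config A `sim_config` (`config$lmm` holds the coefficients).
#' @param seed RNG seed.
#' @param n_subjects,n_sessions,n_trials Cohort dimensions (defaults from
#'   config; trials = training trials per session).
#' @return List: `data` (subject, session, phase, trial_index, o2hb,
#'   rating), `truth` (the coefficient list used).
#' @export
simulate_rating_lmm <- function(config = sim_config(), seed = 1,
                                n_subjects = config$n_subjects,
                                n_sessions = config$n_sessions,
                                n_trials = config$n_trials_per_condition) {
  set.seed(seed)
  lc <- config$lmm
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    b_i <- stats::rnorm(1, 0, lc$subject_sd)
    bp_i <- stats::rnorm(1, 0, lc$bp_sd)
    recs <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      phase <- rep(1:3, times = c(
        n_trials %/% 3 + (n_trials %% 3 >= 1),
        n_trials %/% 3 + (n_trials %% 3 >= 2),
        n_trials %/% 3))
      wp <- stats::rnorm(n_trials, 0, lc$wp_sd)
      o2hb <- bp_i + wp
      r <- numeric(n_trials)
      for (k in seq_len(n_trials)) {
        lag_term <- if (k == 1) 0 else lc$beta_lag * r[k - 1]
        r[k] <- lc$beta0 + lc$beta_session * s + lc$beta_phase * phase[k] +
          lag_term + lc$beta_wp * wp[k] + lc$beta_bp * bp_i + b_i +
          stats::rnorm(1, 0, lc$resid_sd)
      }
      recs[[s]] <- data.frame(subject = i, session = s, phase = phase,
                              trial_index = seq_len(n_trials),
                              o2hb = o2hb, rating = r)
    }
    rows[[i]] <- do.call(rbind, recs)
  }
  list(data = do.call(rbind, rows), truth = lc)
}

#' Simulate a full cohort bundle
#'
#' Orchestrates the generators with per-subject/session derived sub-seeds:
#' contrast records (the inference layer's input), per-trial ratings with
#' session events, intervention logs, cross-over questionnaires, and the
#' ground truth of every injected effect. Identical seed + config gives a
#' bit-identical bundle.
#'
#' @param config A `sim_config`.
#' @param seed Master RNG seed.
#' @return List of class `cohort_bundle`: `contrasts`, `events` (list by
#'   subject/session), `ratings`, `interventions`, `questionnaires`,
#'   `ground_truth`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  cc <- simulate_contrast_cohort(config, derive_seed(seed, salt = 1))
  ratings <- list()
  events <- list()
  set.seed(derive_seed(seed, salt = 9))
  gap_offsets <- matrix(stats::rnorm(config$n_subjects *
                                       length(config$ratings),
                                     0, config$rating_gap_subject_sd),
                        config$n_subjects, length(config$ratings),
                        dimnames = list(NULL, names(config$ratings)))
  for (i in seq_len(config$n_subjects)) {
    for (s in seq_len(config$n_sessions)) {
      ev <- simulate_design(2 * config$n_trials_per_condition, config$block,
                            config$trial_duration, config$talk_gap,
                            seed = derive_seed(seed, i, s, 2))
      be <- simulate_behavior(ev, config, i, s,
                              seed = derive_seed(seed, i, s, 3),
                              gap_offset = gap_offsets[i, ])
      be$subject <- i; be$session <- s
      key <- sprintf("s%02d_sess%d", i, s)
      events[[key]] <- ev
      ratings[[length(ratings) + 1]] <- be
    }
  }
  ratings <- do.call(rbind, ratings)
  n_iv <- config$interventions_per_session * config$n_sessions
  iv <- simulate_interventions(n_iv, config, derive_seed(seed, salt = 4))
  qs <- simulate_questionnaires(config, derive_seed(seed, salt = 5))
  structure(list(contrasts = cc$contrasts, events = events,
                 ratings = ratings, interventions = iv,
                 questionnaires = qs$data,
                 ground_truth = list(contrast = cc$truth,
                                     questionnaires = qs$truth,
                                     ratings = config$ratings,
                                     rating_gap_offsets = gap_offsets),
                 config = config, seed = seed),
            class = "cohort_bundle")
}
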