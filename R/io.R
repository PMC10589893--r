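#' @importFrom utils read.delim write.table packageVersion combn head
NULL

provenance_header <- function(extra = character()) {
  c(sprintf("# generated by fnirstrain %s on %s",
            as.character(utils::packageVersion("fnirstrain")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("# ", extra))
}

write_tsv_with_header <- function(df, path, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(extra), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_comments <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a channel time series as tidy TSV
#'
#' Canonical interchange format: columns `time_s`, `channel`, `band`
#' (wavelength or chromophore label), `value`, plus a provenance comment
#' header. Reading validates the schema and rejects irregular sampling.
#'
#' @param ts A `channel_ts`.
#' @param path File path.
#' @return `write_timeseries`: the path, invisibly. `read_timeseries`:
#'   a `channel_ts`.
#' @export
write_timeseries <- function(ts, path) {
  tt <- time_axis(ts)
  rows <- do.call(rbind, lapply(names(ts$data), function(b) {
    x <- ts$data[[b]]
    data.frame(time_s = rep(tt, times = ncol(x)),
               channel = rep(ts$channels, each = nrow(x)),
               band = b, value = as.vector(x))
  }))
  write_tsv_with_header(rows, path,
                        c(sprintf("fs_hz: %g", ts$fs),
                          sprintf("unit: %s", ts$unit), ts$provenance))
}

#' @rdname write_timeseries
#' @param unit Unit tag to assign on read (default "conc").
#' @export
read_timeseries <- function(path, unit = "conc") {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 20)
  fs_line <- grep("^# fs_hz:", hdr, value = TRUE)
  unit_line <- grep("^# unit:", hdr, value = TRUE)
  if (length(fs_line)) fs <- as.numeric(sub("^# fs_hz:\\s*", "", fs_line[1]))
  else fs <- NA
  if (length(unit_line)) unit <- sub("^# unit:\\s*", "", unit_line[1])
  df <- read_tsv_skip_comments(path)
  req <- c("time_s", "channel", "band", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  bands <- sort(unique(df$band))
  channels <- sort(unique(df$channel))
  times <- sort(unique(df$time_s))
  dt <- diff(times)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("irregular sampling detected")
  }
  if (!is.finite(fs)) fs <- 1 / stats::median(dt)
  data <- lapply(bands, function(b) {
    sub <- df[df$band == b, ]
    m <- matrix(NA_real_, length(times), length(channels))
    m[cbind(match(sub$time_s, times), match(sub$channel, channels))] <- sub$value
    if (anyNA(m)) stop("schema error: missing time x channel cells in band ", b)
    m
  })
  names(data) <- bands
  channel_ts(data, fs = fs, unit = unit, channels = channels)
}

#' Write / read session events (BIDS-style events.tsv)
#'
#' Columns `onset`, `duration`, `trial_type` plus any per-trial rating
#' columns. Rows are sorted by onset on read and the `session_events`
#' invariants (strictly increasing, non-overlapping trials) enforced.
#'
#' @param events A `session_events`.
#' @param path File path.
#' @return `write_events`: path invisibly; `read_events`: `session_events`.
#' @export
write_events <- function(events, path) {
  write_tsv_with_header(events$trials, path, "events")
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_tsv_skip_comments(path)
  req <- c("onset", "duration", "trial_type")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  df$trial_index <- NULL
  session_events(df)
}

#' Write / read contrast records as tidy TSV
#'
#' @param contrasts data.frame subject, session, phase, roi, value.
#' @param path File path.
#' @param extra Extra provenance lines.
#' @return Path / data.frame.
#' @export
write_contrasts <- function(contrasts, path, extra = character()) {
  write_tsv_with_header(contrasts, path, c("contrast records", extra))
}

#' @rdname write_contrasts
#' @export
read_contrasts <- function(path) {
  df <- read_tsv_skip_comments(path)
  req <- c("subject", "session", "phase", "roi", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  df
}

#' Process one session: clean, epoch, aggregate, contrast
#'
#' Runs the preprocessing chain on a concentration-stage recording, then
#' epochs trials, averages channels into ROIs and forms the
#' training-minus-control contrast per session third.
#'
#' @param ts `channel_ts`, unit "conc" (bands O2Hb, HHb).
#' @param events A `session_events`.
#' @param layout A `probe_layout`.
#' @param config A `cleaning_config`.
#' @param window,baseline Epoching windows (s relative to onset).
#' @return List: `contrasts` (phase, roi, value), `trial_means`
#'   (trials x ROI), `channel_trial_means`, `report` (cleaning report).
#' @export
process_session <- function(ts, events, layout,
                            config = cleaning_config(),
                            window = c(5, 40), baseline = c(-5, 0)) {
  cl <- run_cleaning_chain(ts, layout, config)
  tm <- epoch_average(cl$ts, events, window, baseline)
  missing <- cl$ts$channels[cl$ts$bad]
  rm_ <- roi_average(tm, layout, missing_channels = missing)
  ctr <- condition_contrast(rm_, events)
  list(contrasts = ctr, trial_means = rm_, channel_trial_means = tm,
       report = cl$report)
}

#' Forward-model contrast prediction for a noiseless session
#'
#' Predicts the end-to-end ROI contrast of a noiseless simulated session
#' by pushing the known clean effect time course (ROI amplitude x
#' HRF-convolved training boxcar) through the linear stages of the chain
#' only -- band-pass, global-signal reduction, z-transform -- then
#' epoching and contrasting. Serves as the independent oracle for the
#' full chain (which additionally runs QC/interpolation, TDDR and CBSI):
#' on artifact-free input the two must agree closely.
#'
#' @param events A `session_events`.
#' @param layout A `probe_layout`.
#' @param config A `sim_config`.
#' @param session Session index (scales the DLPFC decline).
#' @param cleaning A `cleaning_config` (band edges, global sigma).
#' @param window,baseline Epoching windows.
#' @return data.frame phase, roi, value (predicted contrast, z-units).
#' @export
forward_model_contrast <- function(events, layout, config = sim_config(),
                                   session = 1,
                                   cleaning = cleaning_config(),
                                   window = c(5, 40), baseline = c(-5, 0)) {
  sim <- simulate_session_signal(events, layout, config, subject = 1,
                                 session = session, seed = 1,
                                 noise_scale = 0)
  x <- apply(sim$ts$data$O2Hb, 2, bandpass, fs = sim$ts$fs,
             low = cleaning$bandpass_low, high = cleaning$bandpass_high)
  ts <- channel_ts(list(O2Hb_corr = x), fs = sim$ts$fs, unit = "conc",
                   channels = sim$ts$channels)
  ts <- zscore_channels(global_signal_reduction(ts, layout,
                                                cleaning$global_sigma))
  tm <- epoch_average(ts, events, window, baseline)
  condition_contrast(roi_average(tm, layout), events)
}

#' Run the signal-level pipeline over a simulated cohort
#'
#' Streams subject x session simulated recordings through
#' [simulate_session_signal()] and [process_session()], collecting tidy
#' contrast records. Memory stays bounded: one session's signals at a
#' time.
#'
#' @param config A `sim_config`.
#' @param layout A `probe_layout`.
#' @param seed Master seed (sub-seeds derived per subject/session).
#' @param n_subjects,n_sessions Cohort slice to run (defaults from config).
#' @param noise_scale Forwarded to the signal generator.
#' @param cleaning A `cleaning_config`.
#' @return List: `contrasts` (subject, session, phase, roi, value),
#'   `truth_amplitude` (subject, session, roi, injected amplitude).
#' @export
run_signal_cohort <- function(config = sim_config(), layout = probe_layout(),
                              seed = 1,
                              n_subjects = config$n_subjects,
                              n_sessions = config$n_sessions,
                              noise_scale = 1,
                              cleaning = cleaning_config()) {
  out <- list(); tr <- list()
  for (i in seq_len(n_subjects)) {
    for (s in seq_len(n_sessions)) {
      ev <- simulate_design(2 * config$n_trials_per_condition, config$block,
                            config$trial_duration, config$talk_gap,
                            seed = derive_seed(seed, i, s, 2))
      sim <- simulate_session_signal(ev, layout, config, i, s,
                                     seed = derive_seed(seed, i, s, 6),
                                     noise_scale = noise_scale)
      ps <- process_session(sim$ts, ev, layout, cleaning)
      ctr <- ps$contrasts
      ctr$subject <- i; ctr$session <- s
      out[[length(out) + 1]] <- ctr
      amp_roi <- tapply(sim$truth$amplitude, sim$truth$roi, mean)
      tr[[length(tr) + 1]] <- data.frame(subject = i, session = s,
                                         roi = names(amp_roi),
                                         amplitude = as.numeric(amp_roi))
    }
  }
  list(contrasts = do.call(rbind, out), truth_amplitude = do.call(rbind, tr))
}

# reshape tidy contrasts (subject, session, phase, roi, value) to wide
contrasts_to_wide <- function(df) {
  rois <- unique(df$roi)
  wide <- unique(df[, c("subject", "session", "phase")])
  key_all <- interaction(df$subject, df$session, df$phase)
  key_w <- interaction(wide$subject, wide$session, wide$phase)
  for (r in rois) {
    sub <- df[df$roi == r, ]
    wide[[r]] <- sub$value[match(key_w, interaction(sub$subject, sub$session,
                                                    sub$phase))]
  }
  wide
}

# per subject x session x phase training-minus-control rating means
ratings_contrast <- function(ratings, rating_names) {
  agg <- stats::aggregate(ratings[rating_names],
                          by = list(subject = ratings$subject,
                                    session = ratings$session,
                                    phase = ratings$phase,
                                    trial_type = ratings$trial_type),
                          FUN = mean)
  tr <- agg[agg$trial_type == "training", ]
  ct <- agg[agg$trial_type == "control", ]
  key <- function(d) interaction(d$subject, d$session, d$phase)
  m <- match(key(tr), key(ct))
  out <- tr[, c("subject", "session", "phase")]
  for (rn in rating_names) out[[rn]] <- tr[[rn]] - ct[[rn]][m]
  out
}

#' Run the study's statistical analyses on a cohort bundle
#'
#' End-to-end statistical layer over a [simulate_cohort()] bundle (or any
#' bundle with the same components): repeated-measures MANOVA of the
#' fNIRS ROI contrasts (session x phase), of the subjective-rating
#' contrasts, and of the questionnaires (group x time); chi-squared tests
#' of the intervention log; and lagged mixed models of each rating on the
#' chosen ROI's oxygenation contrast (training-trial records, O2Hb level
#' per session third merged onto trials). Benjamini-Hochberg adjustment
#' is applied within the documented families.
#'
#' @param bundle A `cohort_bundle`.
#' @param lmm_roi ROI whose contrast enters the mixed models
#'   (default "SAC").
#' @param lmm_ratings Ratings to model (default all four).
#' @return List of class `pipeline_results`: `fnirs`, `ratings`,
#'   `questionnaires` (each `rm_manova`), `interventions`
#'   (StatResult rows), `lmm` (list of `lmm_fit` per rating),
#'   `posthoc_questionnaires` (BH-adjusted t-tests).
#' @export
run_pipeline <- function(bundle, lmm_roi = "SAC",
                         lmm_ratings = c("burden", "self_compassion",
                                         "equanimity", "effort")) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  wide <- contrasts_to_wide(bundle$contrasts)
  rois <- unique(bundle$contrasts$roi)
  fnirs <- rm_manova(wide, dv = rois, within = c("session", "phase"))

  rc <- ratings_contrast(bundle$ratings, lmm_ratings)
  ratings <- rm_manova(rc, dv = lmm_ratings, within = c("session", "phase"))

  qs <- bundle$questionnaires
  scales <- setdiff(names(qs), c("subject", "time", "group"))
  quest <- rm_manova(qs, dv = scales, within = "time", between = "group")

  # twelve questionnaire post-hoc comparisons: one BH family
  posthoc <- list()
  for (sc in scales) {
    w <- stats::reshape(qs[, c("subject", "time", sc)], direction = "wide",
                        idvar = "subject", timevar = "time")
    grp <- qs$group[match(w$subject, qs$subject)]
    v1 <- w[[paste0(sc, ".1")]]; v2 <- w[[paste0(sc, ".2")]]
    v3 <- w[[paste0(sc, ".3")]]
    posthoc[[length(posthoc) + 1]] <-
      ttest_with_d(v3, v1, paired = TRUE, effect = paste0(sc, ": t1 vs t3"))
    posthoc[[length(posthoc) + 1]] <-
      ttest_with_d(v2[grp == "treatment_first"], v2[grp == "tau_first"],
                   effect = paste0(sc, ": groups at t2"))
    posthoc[[length(posthoc) + 1]] <-
      ttest_with_d(v3[grp == "treatment_first"], v3[grp == "tau_first"],
                   effect = paste0(sc, ": groups at t3"))
  }
  posthoc <- do.call(rbind, posthoc)
  posthoc$p_corr <- bh_adjust(posthoc$p_raw)

  iv <- bundle$interventions
  ivt <- rbind(
    chisq_tests(as.vector(table(factor(iv$session, levels = 1:8))),
                effect = "interventions across sessions"),
    chisq_tests(as.vector(table(factor(iv$phase, levels = 1:3))),
                effect = "interventions across phases"),
    chisq_tests(as.vector(table(iv$category)),
                effect = "intervention categories"),
    chisq_tests(table(iv$category, iv$phase),
                effect = "category x phase"),
    chisq_tests(table(iv$category, iv$session),
                effect = "category x session"))

  # merge the ROI's phase-level O2Hb contrast onto training trials
  sub <- bundle$contrasts[bundle$contrasts$roi == lmm_roi, ]
  tr <- bundle$ratings[bundle$ratings$trial_type == "training", ]
  m <- match(interaction(tr$subject, tr$session, tr$phase),
             interaction(sub$subject, sub$session, sub$phase))
  tr$o2hb <- sub$value[m]
  lmm <- lapply(lmm_ratings, function(rn) fit_lmm(tr, rn))
  names(lmm) <- lmm_ratings

  structure(list(fnirs = fnirs, ratings = ratings, questionnaires = quest,
                 posthoc_questionnaires = posthoc, interventions = ivt,
                 lmm = lmm),
            class = "pipeline_results")
}
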