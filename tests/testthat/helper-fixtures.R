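# shared fixtures and independent oracles, built in code

# brute-force Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} min(1, p_(j) m / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, po[j] * m / j), numeric(1))
    adj[i] <- min(cand)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# minimal custom layout with explicit coordinates (mm)
toy_layout <- function(pos, probeset = rep("left frontal", nrow(pos)),
                       roi_map = list()) {
  structure(list(
    channels = data.frame(channel = seq_len(nrow(pos)),
                          x_mm = pos[, 1], y_mm = pos[, 2],
                          probeset = probeset, stringsAsFactors = FALSE),
    roi_map = roi_map, interoptode_distance = 30),
    class = "probe_layout")
}

# simple events table: alternating conditions, regular spacing
toy_events <- function(n_trials = 6, spacing = 60, duration = 40,
                       first_onset = 10) {
  session_events(data.frame(
    onset = first_onset + (seq_len(n_trials) - 1) * spacing,
    duration = duration,
    trial_type = rep(c("training", "control"), length.out = n_trials)))
}

# paired t-test oracle for the rm_manova identity
paired_t <- function(x, y) stats::t.test(x, y, paired = TRUE)

# per-scale paired d from a questionnaire long table
paired_d13 <- function(q, scale) {
  w <- stats::reshape(q[, c("subject", "time", scale)], direction = "wide",
                      idvar = "subject", timevar = "time")
  d <- w[[paste0(scale, ".3")]] - w[[paste0(scale, ".1")]]
  mean(d) / stats::sd(d)
}
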