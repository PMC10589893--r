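test_that("trial randomization is balanced within every block of ten", {
  for (s in 1:50) {
    ev <- simulate_design(seed = s)
    cond <- ev$trials$trial_type
    for (b in 0:3) {
      expect_equal(sum(cond[b * 10 + 1:10] == "training"), 5)
    }
  }
  e1 <- simulate_design(seed = 99)
  e2 <- simulate_design(seed = 99)
  expect_identical(e1$trials, e2$trials)
  expect_error(simulate_design(n_trials = 25), "divisible")
  expect_error(simulate_design(block = 5), "even")
})

test_that("first-trial condition is unbiased across seeds", {
  first <- vapply(1:2000, function(s) {
    simulate_design(seed = s)$trials$trial_type[1] == "training"
  }, logical(1))
  p <- mean(first)
  expect_gt(p, 0.5 - 3 * sqrt(0.25 / 2000))
  expect_lt(p, 0.5 + 3 * sqrt(0.25 / 2000))
})

test_that("noiseless behavior generator reproduces its cell-mean model exactly", {
  cfg <- sim_config()
  ev <- simulate_design(seed = 5)
  be <- simulate_behavior(ev, cfg, subject = 1, session = 3, seed = 6,
                          noise_scale = 0)
  rc <- cfg$ratings$burden
  for (i in c(1, 10, 25, 40)) {
    ct <- be$trial_type[i]; ph <- be$phase[i]
    mu <- rc$base + (ct == "training") * rc$gap + rc$sess[[ct]] * 2 +
      rc$phase[[ct]] * (ph - 2) + rc$quad[[ct]] * ((ph - 2)^2 - 2 / 3)
    expect_equal(be$burden[i], unname(mu), tolerance = 1e-12)
  }
  noisy <- simulate_behavior(ev, cfg, seed = 7)
  for (rn in names(cfg$ratings)) {
    expect_true(all(noisy[[rn]] >= 0 & noisy[[rn]] <= 10))
  }
})

test_that("intervention draws converge to the configured phase and session shares", {
  cfg <- sim_config()
  iv <- simulate_interventions(10000, cfg, seed = 8)
  ph <- as.vector(table(iv$phase)) / 10000
  target <- cfg$intervention_phase_weights / sum(cfg$intervention_phase_weights)
  expect_true(all(abs(ph - target) < 0.02))
  # session shares decline overall (first vs last sessions)
  sw <- cfg$intervention_session_weights
  expect_gt(sw[1], sw[8])
  expect_gt(mean(sw[1:4]), mean(sw[5:8]))
  sess <- as.vector(table(factor(iv$session, levels = 1:8))) / 10000
  expect_lt(max(abs(sess - cfg$intervention_session_weights /
                      sum(cfg$intervention_session_weights))), 0.02)
  top <- names(sort(table(iv$category), decreasing = TRUE))[1]
  expect_equal(top, "cognitive reframing / reappraisal")
})

test_that("noiseless questionnaire trajectories equal the configured cross-over", {
  cfg <- sim_config()
  qs <- simulate_questionnaires(cfg, seed = 9, noise_scale = 0)
  q <- qs$data
  for (sc in names(cfg$questionnaires)) {
    cell <- tapply(q[[sc]], list(q$group, q$time), mean)
    expect_equal(cell["treatment_first", ],
                 qs$truth[[sc]]["treatment_first", ],
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(cell["tau_first", ], qs$truth[[sc]]["tau_first", ],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # treatment-first improves t1->t2 then holds; tau-first the reverse order
  bdi <- qs$truth$BDI
  expect_lt(bdi["treatment_first", 2], bdi["treatment_first", 1])
  expect_equal(bdi["treatment_first", 3], bdi["treatment_first", 2])
  expect_equal(bdi["tau_first", 2], bdi["tau_first", 1])
  expect_lt(bdi["tau_first", 3], bdi["tau_first", 2])
})

test_that("questionnaire generator hits its paired effect-size targets on average", {
  ds <- vapply(1:30, function(s) {
    paired_d13(simulate_questionnaires(sim_config(), seed = s)$data, "BDI")
  }, numeric(1))
  expect_lt(abs(mean(ds) - (-1.47)), 0.15)
})

test_that("cross-over design yields the delayed u-shaped group-by-time interaction", {
  hits <- 0
  for (s in 1:15) {
    q <- simulate_questionnaires(sim_config(), seed = 400 + s)$data
    rmv <- rm_manova(q, dv = c("BDI", "SWE", "SCS", "SRQ"),
                     within = "time", between = "group")
    pc <- rmv$polynomial
    # per-scale quadratic interaction contrasts (scales differ in units
    # and direction, so the pooled cross-DV contrast is not meaningful)
    quad_p <- pc$p_raw[pc$effect %in% paste0("group:time:",
                                             c("BDI", "SWE", "SCS", "SRQ"),
                                             ":quadratic")]
    # the weakest scale (SWE, d = 0.88) has ~90% quadratic power on its
    # own, so demand the interaction plus quadratic curvature in at
    # least three of the four scales
    if (rmv$multivariate$p_raw[rmv$multivariate$effect == "group:time"] < 0.05 &&
        sum(quad_p < 0.05) >= 3) hits <- hits + 1
  }
  expect_gte(hits / 15, 0.9)
})

test_that("null contrast cohorts have no systematic contrast", {
  devs <- vapply(1:20, function(s) {
    cc <- simulate_contrast_cohort(sim_config(), seed = 500 + s,
                                   n_subjects = 12, effect_scale = 0)
    mean(cc$contrasts$value)
  }, numeric(1))
  se <- sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 2 * se + 1e-3)
})

test_that("cohort bundles are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_subjects = 3L, n_sessions = 2L)
  b1 <- simulate_cohort(cfg, seed = 77)
  b2 <- simulate_cohort(cfg, seed = 77)
  expect_identical(b1$contrasts, b2$contrasts)
  expect_identical(b1$ratings, b2$ratings)
  expect_identical(b1$questionnaires, b2$questionnaires)
  expect_identical(b1$interventions, b2$interventions)
  b3 <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(b1$contrasts$value, b3$contrasts$value))
})

test_that("session signals contain the configured artifacts and lose them to TDDR", {
  lay <- probe_layout()
  cfg <- sim_config(noise = list(white_sd = 0.1, drift_sd = 0,
                                 cardiac_amp = 0, cardiac_hz = 1.1,
                                 resp_amp = 0, resp_hz = 0.25,
                                 mayer_amp = 0, mayer_hz = 0.1,
                                 spike_rate_per_min = 2, spike_amp = 3,
                                 global_sd = 0))
  ev <- simulate_design(n_trials = 10, block = 10, seed = 51)
  sim <- simulate_session_signal(ev, lay, cfg, seed = 52)
  expect_gt(sum(sim$truth$n_spikes), 0)
  j <- which.max(sim$truth$n_spikes)
  x <- sim$ts$data$O2Hb[, j]
  clean_amp <- sim$truth$amplitude[j] * sim$truth$regressor
  r <- tddr(x, cfg$fs)
  rmse_in <- sqrt(mean((x - clean_amp)^2))
  rmse_out <- sqrt(mean((r$signal - clean_amp)^2))
  expect_lt(rmse_out, rmse_in)
})

test_that("zero-effect session signals give near-zero pipeline contrasts", {
  lay <- probe_layout()
  cfg <- sim_config(effect_session1 = c(lIFG = 0, lDLPFC = 0, rIFG = 0,
                                        rDLPFC = 0, SAC = 0),
                    effect_background = 0, amp_subject_sd = 0)
  vals <- c()
  for (s in 1:3) {
    ev <- simulate_design(n_trials = 10, block = 10,
                          seed = 600 + s)
    sim <- simulate_session_signal(ev, lay, cfg, seed = 700 + s)
    ps <- process_session(sim$ts, ev, lay)
    vals <- c(vals, ps$contrasts$value)
  }
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se + 0.05)
})
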