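test_that("Benjamini-Hochberg matches the brute-force step-up on fixed and random inputs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment is monotone in raw p and order-invariant", {
  set.seed(18)
  p <- runif(15)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  perm <- sample(15)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("t-tests carry the matching Cohen's d", {
  # paired differences 1,2,3: t = 2 / (1/sqrt(3)), d = 2
  r <- ttest_with_d(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$df1, 2)
  expect_equal(r$effect_size, 2)

  g <- c(1.2, 3.4, 2.2, 0.8)
  r2 <- ttest_with_d(g, g)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$effect_size, 0)

  set.seed(19)
  dhat <- replicate(300, {
    r <- ttest_with_d(rnorm(21, 0.8), rnorm(21))
    r$effect_size
  })
  expect_lt(abs(mean(dhat) - 0.8), 0.1)

  expect_error(ttest_with_d(rep(2, 5), rep(1, 5), paired = TRUE),
               "zero-variance")
})

test_that("chi-squared tests match hand-computed values", {
  expect_equal(chisq_tests(c(10, 10, 10))$statistic, 0)
  r <- chisq_tests(c(39, 42, 19))
  # E = 100/3 each: (39-E)^2/E + (42-E)^2/E + (19-E)^2/E
  e <- 100 / 3
  expect_equal(r$statistic, ((39 - e)^2 + (42 - e)^2 + (19 - e)^2) / e,
               tolerance = 1e-10)
  expect_equal(r$df1, 2)
  r2 <- chisq_tests(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r2$statistic, 20)
  expect_equal(r2$df1, 1)
  expect_error(chisq_tests(c(5, -1)), ">= 0")
})

test_that("person mean centering decomposes exactly", {
  pm <- person_mean_center(c(1, 2, 3), rep("a", 3))
  expect_equal(pm$bp, rep(2, 3))
  expect_equal(pm$wp, c(-1, 0, 1))
  pm1 <- person_mean_center(5, "a")
  expect_equal(pm1$wp, 0); expect_equal(pm1$bp, 5)
  set.seed(20)
  v <- rnorm(100); s <- sample(letters[1:7], 100, TRUE)
  pm2 <- person_mean_center(v, s)
  expect_equal(pm2$wp + pm2$bp, v, tolerance = 1e-12)
  expect_true(all(abs(tapply(pm2$wp, s, sum)) < 1e-12))
})

test_that("Huynh-Feldt epsilon: bounds and limiting cases", {
  # k = 2: sphericity automatic
  expect_equal(huynh_feldt_epsilon(matrix(2.3), n = 15, k = 2)$epsilon, 1)
  # compound symmetry: orthonormalized covariance is spherical
  expect_equal(huynh_feldt_epsilon(diag(0.7, 3), n = 40, k = 4)$gg, 1)
  expect_equal(huynh_feldt_epsilon(diag(0.7, 3), n = 40, k = 4)$epsilon, 1)
  # strongly heterogeneous AR covariance: epsilon < 1 but above 1/(k-1)
  k <- 5
  sds <- c(1, 2, 4, 8, 16)
  Sig <- outer(sds, sds) * 0.8^abs(outer(1:k, 1:k, "-"))
  C <- t(stats::contr.poly(k))
  S <- C %*% Sig %*% t(C)
  hf <- huynh_feldt_epsilon(S, n = 30, k = k)
  expect_lt(hf$epsilon, 1)
  expect_gt(hf$epsilon, 1 / (k - 1))
  expect_error(huynh_feldt_epsilon(matrix(1), n = 1, k = 2), "n > 1")
})

test_that("polynomial contrasts isolate trend orders", {
  n <- 10
  lin <- matrix(rep(c(1, 2, 3, 4), each = n), n, 4)
  pc <- polynomial_contrast_tests(lin)
  expect_gt(pc$statistic[pc$order == "linear"], 1e6)
  expect_equal(pc$value[pc$order == "quadratic"], 0, tolerance = 1e-12)

  flat <- matrix(2, n, 4)
  expect_true(all(abs(polynomial_contrast_tests(flat)$value) < 1e-12))

  ush <- matrix(rep(c(2, 0, 2), each = n), n, 3)
  pcu <- polynomial_contrast_tests(ush)
  expect_equal(pcu$value[pcu$order == "linear"], 0, tolerance = 1e-12)
  expect_gt(abs(pcu$value[pcu$order == "quadratic"]), 1)

  # orders above cubic computed but flagged unreported
  wide <- matrix(rnorm(6 * n), n, 6)
  pcw <- polynomial_contrast_tests(wide)
  expect_true(all(pcw$reported[pcw$order %in% c("linear", "quadratic", "cubic")]))
  expect_false(any(pcw$reported[pcw$order %in% c("order4", "order5")]))
})

test_that("one-DV two-level rmMANOVA reproduces the paired t-test", {
  set.seed(23)
  n <- 17
  x <- rnorm(n); y <- rnorm(n, 0.4)
  d <- data.frame(subject = rep(seq_len(n), each = 2),
                  cond = rep(1:2, n), y = as.vector(rbind(x, y)))
  rmv <- rm_manova(d, dv = "y", within = "cond")
  tt <- paired_t(x, y)
  eff <- rmv$multivariate[rmv$multivariate$effect == "cond", ]
  expect_equal(eff$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(eff$statistic, 1 / (1 + unname(tt$statistic)^2 / (n - 1)),
               tolerance = 1e-8)
  expect_equal(eff$df1, 1); expect_equal(eff$df2, n - 1)
  # univariate follow-up agrees too
  uni <- rmv$univariate[rmv$univariate$effect == "cond", ]
  expect_equal(uni$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(uni$epsilon, 1)
})

test_that("rmMANOVA detects an injected linear session effect in the affected DVs", {
  hits_multi <- 0; hits_dv <- 0
  reps <- 25
  for (r in seq_len(reps)) {
    set.seed(300 + r)
    n <- 30; k <- 5
    base <- expand.grid(subject = 1:n, session = 1:k)
    d <- base
    for (j in 1:5) {
      slope <- if (j <= 2) 0.25 else 0
      d[[paste0("dv", j)]] <- slope * base$session +
        rnorm(n)[base$subject] + rnorm(nrow(base), 0, 0.8)
    }
    rmv <- rm_manova(d, dv = paste0("dv", 1:5), within = "session")
    ms <- rmv$multivariate
    if (ms$p_raw[ms$effect == "session"] < 0.05) hits_multi <- hits_multi + 1
    us <- rmv$univariate
    p12 <- us$p_raw[us$effect == "session" & us$dv %in% c("dv1", "dv2")]
    if (all(p12 < 0.05)) hits_dv <- hits_dv + 1
  }
  expect_gte(hits_multi / reps, 0.9)
  expect_gte(hits_dv / reps, 0.9)
})

test_that("rmMANOVA with a between factor recovers a group-by-time interaction", {
  set.seed(26)
  n <- 40
  d <- expand.grid(subject = 1:n, time = 1:3)
  d$group <- ifelse(d$subject <= n / 2, "a", "b")
  # u-shaped group difference: group a dips at time 2
  d$y1 <- ifelse(d$group == "a" & d$time == 2, -1.5, 0) +
    rnorm(n)[d$subject] + rnorm(nrow(d), 0, 0.7)
  d$y2 <- rnorm(n)[d$subject] + rnorm(nrow(d), 0, 0.7)
  rmv <- rm_manova(d, dv = c("y1", "y2"), within = "time", between = "group")
  ms <- rmv$multivariate
  expect_lt(ms$p_raw[ms$effect == "group:time"], 0.01)
  # quadratic interaction contrast carries it
  pc <- rmv$polynomial
  row <- pc[pc$effect == "group:time:y1:quadratic", ]
  expect_lt(row$p_raw, 0.01)
})

test_that("balanced-design validation rejects incomplete cells", {
  d <- data.frame(subject = c(1, 1, 2), cond = c(1, 2, 1), y = rnorm(3))
  expect_error(rm_manova(d, dv = "y", within = "cond"), "incomplete")
})

test_that("mixed model with no between-subject variance matches OLS", {
  cfg <- sim_config(lmm = list(beta0 = 2, beta_session = -0.2,
                               beta_phase = 0.3, beta_lag = 0.25,
                               beta_wp = -0.5, beta_bp = 0.5,
                               bp_sd = 0.4, wp_sd = 0.5,
                               subject_sd = 0, resid_sd = 1))
  sim <- simulate_rating_lmm(cfg, seed = 27, n_subjects = 15,
                             n_sessions = 3, n_trials = 8)
  fit <- suppressMessages(suppressWarnings(fit_lmm(sim$data, "rating")))
  fr <- fit$fit@frame
  ols <- lm(resp ~ session + phase + session:phase + lag + wp + bp +
              session:wp + phase:wp + session:bp + phase:bp, data = fr)
  expect_lt(as.data.frame(lme4::VarCorr(fit$fit))$vcov[1], 0.05)
  expect_equal(unname(lme4::fixef(fit$fit)), unname(coef(ols)),
               tolerance = 1e-5)
})

test_that("mixed model recovers injected coefficients (pooled over replicate cohorts)", {
  terms <- c("session", "phase", "lag", "wp")
  reps <- 5
  est <- matrix(0, reps, length(terms), dimnames = list(NULL, terms))
  ses <- est
  tr <- NULL
  for (s in seq_len(reps)) {
    sim <- simulate_rating_lmm(sim_config(), seed = s, n_subjects = 25,
                               n_sessions = 6, n_trials = 15)
    tr <- sim$truth
    co <- fit_lmm(sim$data, "rating")$coefficients
    est[s, ] <- co$beta[match(terms, co$term)]
    ses[s, ] <- co$se[match(terms, co$term)]
  }
  truth <- c(tr$beta_session, tr$beta_phase, tr$beta_lag, tr$beta_wp)
  pooled_se <- colMeans(ses) / sqrt(reps)
  expect_true(all(abs(colMeans(est) - truth) < 2 * pooled_se))
})

test_that("marginal R2 tracks the fixed-effect variance share", {
  # no fixed effects: near zero
  set.seed(29)
  d0 <- data.frame(subject = rep(1:30, each = 10),
                   x = rnorm(300), y = rnorm(300) + rnorm(30)[rep(1:30, each = 10)])
  f0 <- lmerTest::lmer(y ~ x + (1 | subject), data = d0)
  expect_lt(marginal_r2(f0), 0.05)

  # pure fixed effect, no noise: near one
  d1 <- data.frame(subject = rep(1:10, each = 10), x = rnorm(100))
  d1$y <- 2 * d1$x + rnorm(100, 0, 1e-4)
  f1 <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ x + (1 | subject), data = d1)))
  expect_gt(marginal_r2(f1), 0.99)

  # 50/25/25 variance partition
  set.seed(30)
  ns <- 150; no <- 20
  d2 <- data.frame(subject = rep(seq_len(ns), each = no),
                   x = rnorm(ns * no, 0, 1))
  d2$y <- sqrt(2) * d2$x + rnorm(ns, 0, 1)[d2$subject] + rnorm(ns * no, 0, 1)
  f2 <- lmerTest::lmer(y ~ x + (1 | subject), data = d2)
  expect_lt(abs(marginal_r2(f2) - 0.5), 0.05)
})
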