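#' @importFrom stats pf pt var sd median na.omit coef as.formula
NULL

# one-row result record shared by all test families
stat_result <- function(effect, test, statistic, df1, df2 = NA_real_,
                        epsilon = NA_real_, p_raw, effect_size = NA_real_,
                        es_type = NA_character_, dv = NA_character_,
                        order = NA_character_) {
  data.frame(effect = effect, test = test, statistic = statistic,
             df1 = df1, df2 = df2, epsilon = epsilon, p_raw = p_raw,
             p_corr = NA_real_, effect_size = effect_size,
             es_type = es_type, dv = dv, order = order,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values
#' (delegates to [stats::p.adjust()]); the family is defined by the call.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values in input order, each `>=` its raw value.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH", n = m)
}

#' t-test with Cohen's d
#'
#' Paired (or one-sample) and independent t-tests with the matching
#' standardized effect size: paired `d = mean(diff)/sd(diff)`, one-sample
#' `d = mean(x)/sd(x)`, independent `d = (mean(x)-mean(y))/sd_pooled`.
#'
#' @param x,y Numeric vectors (`y = NULL` for one-sample).
#' @param paired Logical.
#' @param effect Label for the result row.
#' @return One-row StatResult data.frame (statistic = t, df, p_raw,
#'   effect_size = d).
#' @export
ttest_with_d <- function(x, y = NULL, paired = FALSE, effect = "t-test") {
  if (paired) {
    if (is.null(y) || length(x) != length(y)) stop("paired test needs equal-length x, y")
    x <- x - y
    y <- NULL
  }
  if (is.null(y)) {
    if (length(x) < 2) stop("need n >= 2")
    s <- sd(x)
    if (s == 0) stop("zero-variance denominator")
    tt <- stats::t.test(x)
    d <- mean(x) / s
  } else {
    if (length(x) < 2 || length(y) < 2) stop("both groups need n >= 2")
    tt <- stats::t.test(x, y, var.equal = TRUE)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    if (sp == 0) stop("zero-variance denominator")
    d <- (mean(x) - mean(y)) / sp
  }
  stat_result(effect, "t", unname(tt$statistic), unname(tt$parameter),
              p_raw = tt$p.value, effect_size = d, es_type = "cohens_d")
}

#' Chi-squared tests of count tables
#'
#' Goodness-of-fit against given (default uniform) proportions for a
#' vector of counts, or independence for a 2D table. No continuity
#' correction (matching hand-computed `sum((O-E)^2/E)`).
#'
#' @param counts Non-negative counts: vector (goodness-of-fit) or matrix
#'   (independence).
#' @param p Expected proportions for the 1D case (default uniform).
#' @param effect Label for the result row.
#' @return One-row StatResult data.frame (statistic = chi-squared).
#' @export
chisq_tests <- function(counts, p = NULL, effect = "chisq") {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (is.matrix(counts)) {
    exp_cells <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (any(exp_cells == 0)) stop("zero expected cell")
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  } else {
    if (is.null(p)) p <- rep(1 / length(counts), length(counts))
    if (any(p * sum(counts) == 0)) stop("zero expected cell")
    ct <- suppressWarnings(stats::chisq.test(counts, p = p))
  }
  stat_result(effect, "chisq", unname(ct$statistic), unname(ct$parameter),
              p_raw = ct$p.value)
}

#' Within/between-person decomposition by person mean centering
#'
#' Splits a time-varying predictor into a between-person component (the
#' subject mean) and a within-person deviation (observation minus subject
#' mean). `wp + bp` reconstructs the input exactly and `wp` sums to zero
#' within every subject.
#'
#' @param values Numeric vector.
#' @param subject Grouping vector of the same length.
#' @return List with `wp` and `bp` vectors (same order as input).
#' @export
person_mean_center <- function(values, subject) {
  if (!length(values)) stop("empty input")
  bp <- stats::ave(values, subject)
  list(wp = values - bp, bp = bp)
}

#' Huynh-Feldt sphericity correction
#'
#' Greenhouse-Geisser epsilon from the covariance of orthonormalized
#' within-subject contrast scores, followed by the Huynh-Feldt adjustment,
#' capped at 1. With k = 2 levels epsilon is exactly 1.
#'
#' @param S Covariance matrix (q x q, q = k - 1) of the orthonormal
#'   contrast scores.
#' @param n Number of subjects contributing to `S` (use n - g + 1 with g
#'   groups).
#' @param k Number of factor levels (q + 1).
#' @return List: `gg`, `hf`, `epsilon` (= min(1, hf)).
#' @export
huynh_feldt_epsilon <- function(S, n, k) {
  q <- k - 1
  if (q < 1) stop("need k >= 2 levels")
  if (n <= 1) stop("need n > 1")
  S <- as.matrix(S)
  stopifnot(nrow(S) == q)
  gg <- sum(diag(S))^2 / (q * sum(S * S))
  hf <- (n * q * gg - 2) / (q * (n - 1 - q * gg))
  list(gg = gg, hf = hf, epsilon = min(1, hf))
}

# Wilks lambda with Rao's F approximation.
# H, E: p x p hypothesis / error SSCP; qh: hypothesis df; v: error df.
wilks_rao <- function(H, E, qh, v) {
  p <- nrow(E)
  if (!is.finite(rcond(E)) || rcond(E) < 1e-12) {
    stop("singular error matrix: reduce the number of DVs or levels")
  }
  lambda <- det(E) / det(E + H)
  s2 <- (p^2 * qh^2 - 4) / (p^2 + qh^2 - 5)
  s <- if (p^2 + qh^2 - 5 > 0 && s2 > 0) sqrt(s2) else 1
  df1 <- p * qh
  df2 <- s * (v - (p - qh + 1) / 2) - (df1 - 2) / 2
  lam_s <- lambda^(1 / s)
  Fv <- ((1 - lam_s) / lam_s) * df2 / df1
  list(lambda = lambda, F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE),
       etap2 = 1 - lam_s, s = s)
}

# orthonormal polynomial contrast rows for k equally spaced levels
poly_contrast_matrix <- function(k) t(stats::contr.poly(k))

#' Polynomial contrast tests over equally spaced levels
#'
#' Applies orthonormal polynomial coefficients (linear, quadratic, cubic,
#' ...) to per-subject level means and tests each order against zero with
#' a one-sample F test (optionally a group-difference F when `between` is
#' given). Orders above `max_report_order` are computed but marked
#' unreported, mirroring the analysis convention that higher orders
#' reflect spurious fluctuation.
#'
#' @param scores Matrix subjects x levels of per-subject means.
#' @param between Optional group factor (length = subjects) adding
#'   group-by-order interaction tests.
#' @param max_report_order Highest order flagged as reportable (default 3).
#' @param effect Label prefix.
#' @return data.frame of StatResult rows plus columns `value` (mean
#'   contrast score) and `reported`.
#' @export
polynomial_contrast_tests <- function(scores, between = NULL,
                                      max_report_order = 3,
                                      effect = "level") {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  n <- nrow(scores)
  if (k < 2) stop("need >= 2 levels")
  C <- poly_contrast_matrix(k)
  order_names <- c("linear", "quadratic", "cubic",
                   if (k > 4) paste0("order", 4:(k - 1)))[seq_len(k - 1)]
  rows <- list()
  for (o in seq_len(k - 1)) {
    s <- as.vector(scores %*% C[o, ])
    if (is.null(between)) {
      ss_eff <- n * mean(s)^2
      ss_err <- sum((s - mean(s))^2)
      Fv <- ss_eff / (ss_err / (n - 1))
      r <- stat_result(paste0(effect, ":", order_names[o]), "F", Fv,
                       1, n - 1, p_raw = pf(Fv, 1, n - 1, lower.tail = FALSE),
                       effect_size = ss_eff / (ss_eff + ss_err),
                       es_type = "etap2", order = order_names[o])
      r$value <- mean(s)
      rows[[length(rows) + 1]] <- r
    } else {
      g <- as.factor(between)
      ng <- table(g)
      gm <- tapply(s, g, mean)
      grand <- mean(s)
      ss_err <- sum((s - gm[g])^2)
      df_err <- n - nlevels(g)
      # grand-mean (within) test and group interaction test per order
      ss_w <- n * grand^2
      Fw <- ss_w / (ss_err / df_err)
      rw <- stat_result(paste0(effect, ":", order_names[o]), "F", Fw, 1,
                        df_err, p_raw = pf(Fw, 1, df_err, lower.tail = FALSE),
                        effect_size = ss_w / (ss_w + ss_err),
                        es_type = "etap2", order = order_names[o])
      rw$value <- grand
      ss_g <- sum(ng * (gm - grand)^2)
      Fg <- (ss_g / (nlevels(g) - 1)) / (ss_err / df_err)
      rg <- stat_result(paste0("group:", effect, ":", order_names[o]), "F",
                        Fg, nlevels(g) - 1, df_err,
                        p_raw = pf(Fg, nlevels(g) - 1, df_err, lower.tail = FALSE),
                        effect_size = ss_g / (ss_g + ss_err),
                        es_type = "etap2", order = order_names[o])
      rg$value <- unname(diff(gm))[1]
      rows[[length(rows) + 1]] <- rw
      rows[[length(rows) + 1]] <- rg
    }
  }
  out <- do.call(rbind, rows)
  out$reported <- match(out$order, order_names) <= max_report_order
  out
}

# build the cell-order and per-subject cell-mean array for rm_manova
# returns list(Y = n x K x p array, cells = data.frame of cell levels)
build_cell_array <- function(data, dv, within, subject) {
  for (w in within) data[[w]] <- as.factor(data[[w]])
  data[[subject]] <- as.factor(data[[subject]])
  cells <- do.call(expand.grid,
                   c(rev(lapply(data[within], levels)),
                     list(stringsAsFactors = FALSE)))
  names(cells) <- rev(within)
  cells <- cells[, within, drop = FALSE]  # last factor varies fastest
  key_cells <- interaction(cells[within], drop = FALSE, lex.order = TRUE)
  subj <- levels(data[[subject]])
  n <- length(subj); K <- nrow(cells); p <- length(dv)
  Y <- array(NA_real_, c(n, K, p),
             dimnames = list(subj, NULL, dv))
  for (i in seq_len(n)) {
    di <- data[data[[subject]] == subj[i], , drop = FALSE]
    m <- match(key_cells, interaction(di[within], drop = FALSE, lex.order = TRUE))
    if (anyNA(m)) stop("incomplete within-cells for subject ", subj[i])
    if (anyDuplicated(interaction(di[within], lex.order = TRUE))) {
      stop("multiple rows per cell for subject ", subj[i],
           "; aggregate to cell means first")
    }
    for (j in seq_len(p)) Y[i, , j] <- di[[dv[j]]][m]
  }
  list(Y = Y, cells = cells, subjects = subj)
}

# kronecker contrast for an effect: subset of within factors
effect_contrast <- function(within, levels_k, effect_factors) {
  C <- matrix(1, 1, 1)
  for (w in within) {
    k <- levels_k[[w]]
    M <- if (w %in% effect_factors) poly_contrast_matrix(k)
         else matrix(1 / sqrt(k), 1, k)
    C <- C %x% M
  }
  C
}

#' Repeated-measures (M)ANOVA via orthonormal contrast transformation
#'
#' For each within-subject effect, per-subject cell means are transformed
#' by the Kronecker product of orthonormal polynomial contrasts (effect
#' factors) and normalized unit vectors (averaged factors). The
#' transformed rows are treated as multivariate observations over the
#' dependent variables: Wilks lambda = det(E)/det(E+H) with H the
#' hypothesis and E the pooled within-cell error cross-products, Rao's F
#' approximation, and multivariate partial eta squared `1 - lambda^(1/s)`
#' -- the convention of mainstream GLM repeated-measures software.
#' Univariate follow-ups per DV use Huynh-Feldt-corrected degrees of
#' freedom. The "constant" effect tests the grand mean of the (possibly
#' contrast-coded) data against zero -- with difference scores as input it
#' is the main effect of the condition contrast.
#'
#' @param data Long-format data.frame: one row per subject x within-cell,
#'   one column per dependent variable.
#' @param dv Character vector of dependent-variable columns.
#' @param within Character vector of within-subject factor columns.
#' @param between Optional between-subject factor column (e.g. group).
#' @param subject Subject id column (default "subject").
#' @param contrasts Logical: add polynomial contrast follow-ups for
#'   single-factor effects (default TRUE).
#' @return List of class `rm_manova`:
#'   `multivariate` (Wilks rows per effect), `univariate`
#'   (HF-corrected F rows per effect x DV), `polynomial` (contrast
#'   follow-ups), `n`, `design`.
#' @export
rm_manova <- function(data, dv, within, between = NULL, subject = "subject",
                      contrasts = TRUE) {
  stopifnot(all(c(dv, within, subject, between) %in% names(data)))
  ca <- build_cell_array(data, dv, within, subject)
  Y <- ca$Y
  n <- dim(Y)[1]; K <- dim(Y)[2]; p <- dim(Y)[3]
  levels_k <- lapply(within, function(w) nlevels(as.factor(data[[w]])))
  names(levels_k) <- within
  grp <- NULL
  if (!is.null(between)) {
    gtab <- unique(data[, c(subject, between)])
    grp <- as.factor(gtab[[between]][match(ca$subjects, gtab[[subject]])])
    if (any(table(grp) < 2)) stop("need >= 2 subjects per group")
  }
  G <- if (is.null(grp)) 1L else nlevels(grp)

  effects <- list(constant = character(0))
  for (m in seq_along(within)) {
    for (cmb in utils::combn(within, m, simplify = FALSE)) {
      effects[[paste(cmb, collapse = ":")]] <- cmb
    }
  }

  multi <- list(); uni <- list(); polys <- list()
  for (en in names(effects)) {
    C <- effect_contrast(within, levels_k, effects[[en]])
    q <- nrow(C)
    # transformed scores: n x q x p
    Z <- array(0, c(n, q, p))
    for (i in seq_len(n)) Z[i, , ] <- C %*% Y[i, , ]

    # multivariate test(s)
    zbar_r <- apply(Z, c(2, 3), mean)          # q x p row means
    if (is.null(grp)) {
      E <- matrix(0, p, p)
      for (r in seq_len(q)) {
        Zr <- matrix(Z[, r, ], nrow = n)
        E <- E + crossprod(sweep(Zr, 2, zbar_r[r, ]))
      }
      H <- n * crossprod(matrix(zbar_r, nrow = q))
      wt <- wilks_rao(H, E, qh = q, v = q * (n - 1))
      multi[[length(multi) + 1]] <- cbind(
        stat_result(en, "Wilks", wt$lambda, wt$df1, wt$df2,
                    p_raw = wt$p, effect_size = wt$etap2, es_type = "etap2"),
        F = wt$F)
    } else {
      # pooled within-group error; effect and effect-x-group hypotheses
      E <- matrix(0, p, p); Hw <- matrix(0, p, p); Hg <- matrix(0, p, p)
      for (r in seq_len(q)) {
        Zr <- matrix(Z[, r, ], nrow = n)
        gm <- apply(Zr, 2, function(v) tapply(v, grp, mean))
        gm <- matrix(gm, nrow = G)
        Dr <- Zr - gm[as.integer(grp), , drop = FALSE]
        E <- E + crossprod(Dr)
        Hw <- Hw + n * tcrossprod(zbar_r[r, ])
        ng <- as.numeric(table(grp))
        dev <- sweep(gm, 2, zbar_r[r, ])
        Hg <- Hg + crossprod(dev * sqrt(ng))
      }
      v <- q * (n - G)
      wtw <- wilks_rao(Hw, E, qh = q, v = v)
      wtg <- wilks_rao(Hg, E, qh = q * (G - 1), v = v)
      multi[[length(multi) + 1]] <- cbind(
        stat_result(en, "Wilks", wtw$lambda, wtw$df1, wtw$df2,
                    p_raw = wtw$p, effect_size = wtw$etap2, es_type = "etap2"),
        F = wtw$F)
      gname <- paste0(between, ":", if (en == "constant") "" else en)
      gname <- sub(":$", "", gname)
      multi[[length(multi) + 1]] <- cbind(
        stat_result(gname, "Wilks", wtg$lambda, wtg$df1, wtg$df2,
                    p_raw = wtg$p, effect_size = wtg$etap2, es_type = "etap2"),
        F = wtg$F)
    }

    # univariate follow-ups per DV with HF correction
    for (j in seq_len(p)) {
      Zj <- matrix(Z[, , j], nrow = n)
      if (is.null(grp)) {
        mns <- colMeans(Zj)
        ss_eff <- n * sum(mns^2)
        ss_err <- sum(sweep(Zj, 2, mns)^2)
        df_err_units <- n - 1
      } else {
        mns <- colMeans(Zj)
        gm <- apply(Zj, 2, function(v) tapply(v, grp, mean))
        gm <- matrix(gm, nrow = G)
        ss_eff <- n * sum(mns^2)
        ss_err <- sum((Zj - gm[as.integer(grp), , drop = FALSE])^2)
        df_err_units <- n - G
      }
      eps <- 1
      if (q > 1) {
        Sw <- if (is.null(grp)) stats::cov(Zj) else {
          Zc <- Zj - gm[as.integer(grp), , drop = FALSE]
          crossprod(Zc) / (n - G)
        }
        eps <- huynh_feldt_epsilon(Sw, n - G + 1, q + 1)$epsilon
      }
      Fv <- (ss_eff / q) / (ss_err / (q * df_err_units))
      uni[[length(uni) + 1]] <- stat_result(
        en, "F", Fv, eps * q, eps * q * df_err_units, epsilon = eps,
        p_raw = pf(Fv, eps * q, eps * q * df_err_units, lower.tail = FALSE),
        effect_size = ss_eff / (ss_eff + ss_err), es_type = "etap2", dv = dv[j])
      if (!is.null(grp)) {
        ss_g <- sum(colSums((gm - matrix(mns, G, q, byrow = TRUE))^2 *
                              as.numeric(table(grp))))
        Fg <- (ss_g / (q * (G - 1))) / (ss_err / (q * df_err_units))
        uni[[length(uni) + 1]] <- stat_result(
          paste0(between, ":", en), "F", Fg, eps * q * (G - 1),
          eps * q * df_err_units, epsilon = eps,
          p_raw = pf(Fg, eps * q * (G - 1), eps * q * df_err_units,
                     lower.tail = FALSE),
          effect_size = ss_g / (ss_g + ss_err), es_type = "etap2", dv = dv[j])
      }
    }

    # polynomial follow-ups for single-factor effects
    if (contrasts && length(effects[[en]]) == 1) {
      w <- effects[[en]]
      k <- levels_k[[w]]
      # per-subject means across the levels of w (averaging other factors)
      lvl_scores <- matrix(0, n, k)
      lev <- levels(as.factor(data[[w]]))
      for (li in seq_len(k)) {
        sel <- ca$cells[[w]] == lev[li]
        for (j in seq_len(p)) {
          lvl_scores[, li] <- lvl_scores[, li] +
            rowMeans(matrix(Y[, sel, j], nrow = n)) / p
        }
      }
      pc <- polynomial_contrast_tests(lvl_scores, between = grp,
                                      effect = en)
      polys[[length(polys) + 1]] <- pc
      for (j in seq_len(p)) {
        lvl_j <- sapply(seq_len(k), function(li) {
          rowMeans(matrix(Y[, ca$cells[[w]] == lev[li], j], nrow = n))
        })
        pcj <- polynomial_contrast_tests(lvl_j, between = grp,
                                         effect = paste0(en, ":", dv[j]))
        pcj$dv <- dv[j]
        polys[[length(polys) + 1]] <- pcj
      }
    }
  }

  structure(list(multivariate = do.call(rbind, multi),
                 univariate = do.call(rbind, uni),
                 polynomial = if (length(polys)) do.call(rbind, polys),
                 n = n,
                 design = list(within = within, between = between,
                               dv = dv, levels = levels_k)),
            class = "rm_manova")
}

#' @export
print.rm_manova <- function(x, ...) {
  cat("Repeated-measures MANOVA (n = ", x$n, ")\n", sep = "")
  cat("Multivariate tests (Wilks):\n")
  print(x$multivariate[, c("effect", "statistic", "F", "df1", "df2",
                           "p_raw", "effect_size")], digits = 4)
  invisible(x)
}

#' Lagged linear mixed model of subjective ratings
#'
#' Fits, for one rating and one ROI's corrected-O2Hb contrast, the model
#' `rating ~ session + phase + session:phase + rating_lagged + WP_O2Hb +
#' BP_O2Hb + session:WP + phase:WP + session:BP + phase:BP +
#' (1 | subject)` by REML with Satterthwaite degrees of freedom
#' (lmerTest). Session (1-8) and phase (1-3) enter as numeric covariates.
#' The oxygenation predictor is split by person mean centering into a
#' within-person deviation (WP) and a between-person mean (BP,
#' grand-mean-centered by default). The lagged rating is computed within
#' subject x session (no lag across session boundaries); first trials per
#' session are dropped.
#'
#' @param data data.frame of training-trial records with columns
#'   `subject`, `session`, `phase`, `trial_index`, `o2hb`, and the
#'   response column.
#' @param response Name of the rating column.
#' @param include_threeway Also include the three-way
#'   session:phase:WP/BP terms (default FALSE).
#' @param center_bp Grand-mean center BP before entry (default TRUE).
#' @return List of class `lmm_fit`: `fit` (lmerMod), `coefficients`
#'   (beta, SE, Satterthwaite df, t, p per term), `marginal_r2`, `n_obs`,
#'   `n_subjects`.
#' @export
fit_lmm <- function(data, response, include_threeway = FALSE,
                    center_bp = TRUE) {
  req <- c("subject", "session", "phase", "trial_index", "o2hb", response)
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[order(data$subject, data$session, data$trial_index), ]
  pm <- person_mean_center(d$o2hb, d$subject)
  d$wp <- pm$wp
  d$bp <- if (center_bp) pm$bp - mean(pm$bp) else pm$bp
  grp <- interaction(d$subject, d$session)
  d$lag <- stats::ave(d[[response]], grp,
                      FUN = function(v) c(NA, v[-length(v)]))
  d <- d[!is.na(d$lag), ]
  if (any(table(d$subject) < 2)) stop("need >= 2 observations per subject after lagging")
  d$resp <- d[[response]]
  rhs <- "session + phase + session:phase + lag + wp + bp + session:wp + phase:wp + session:bp + phase:bp"
  if (include_threeway) rhs <- paste(rhs, "+ session:phase:wp + session:phase:bp")
  form <- as.formula(paste("resp ~", rhs, "+ (1 | subject)"))
  fit <- lmerTest::lmer(form, data = d, REML = TRUE)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p_raw = sm[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, coefficients = coefs,
                 marginal_r2 = marginal_r2(fit),
                 n_obs = nrow(d),
                 n_subjects = length(unique(d$subject))),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Mixed model (", x$n_obs, " obs, ", x$n_subjects,
      " subjects), marginal R2 = ", round(x$marginal_r2, 3), "\n", sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Marginal R-squared of a mixed model
#'
#' Variance explained by the fixed effects:
#' `var(X beta) / (var(X beta) + sum(random-effect variances) + residual
#' variance)`.
#'
#' @param fit A merMod fit.
#' @return Numeric in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  X <- lme4::getME(fit, "X")
  var_f <- var(as.vector(X %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  var_f / (var_f + var_r + var_e)
}
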