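#!/usr/bin/env Rscript
# Repeated-measures MANOVA of the training-minus-control contrasts:
# fNIRS ROI contrasts and subjective-rating contrasts over
# session (1-8) x session phase (1-3), with polynomial follow-ups.

suppressMessages(library(fnirstrain))

contrasts <- read_contrasts("results/cohort/contrasts.tsv")
ratings <- read.delim("results/cohort/ratings.tsv")
dir.create("results", showWarnings = FALSE)

wide <- fnirstrain:::contrasts_to_wide(contrasts)
rois <- unique(contrasts$roi)
fn <- rm_manova(wide, dv = rois, within = c("session", "phase"))
cat("fNIRS contrasts, multivariate tests:\n")
print(fn$multivariate[, c("effect", "statistic", "F", "df1", "df2",
                          "p_raw", "effect_size")], digits = 3)
uni <- fn$univariate
uni$p_corr <- ave(uni$p_raw, uni$effect, FUN = bh_adjust)  # one family per effect
write.table(fn$multivariate, "results/fnirs_multivariate.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(uni, "results/fnirs_univariate.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fn$polynomial, "results/fnirs_polynomial.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sess_dlpfc <- subset(uni, effect == "session" & dv %in% c("lDLPFC", "rDLPFC"))
cat("\nDLPFC session decline (Huynh-Feldt-corrected):\n")
print(sess_dlpfc[, c("dv", "statistic", "df1", "df2", "epsilon",
                     "p_raw", "p_corr", "effect_size")], digits = 3)

rc <- fnirstrain:::ratings_contrast(
  ratings, c("burden", "self_compassion", "equanimity", "effort"))
rt <- rm_manova(rc, dv = c("burden", "self_compassion", "equanimity",
                           "effort"), within = c("session", "phase"))
cat("\nrating contrasts, multivariate tests:\n")
print(rt$multivariate[, c("effect", "statistic", "F", "df1", "df2",
                          "p_raw", "effect_size")], digits = 3)
write.table(rt$multivariate, "results/ratings_multivariate.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rt$univariate, "results/ratings_univariate.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
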