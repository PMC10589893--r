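#!/usr/bin/env Rscript
# Cross-over questionnaire analysis (group x time rmMANOVA, twelve
# BH-corrected post-hoc t-tests) and chi-squared tests of the
# intervention log.

suppressMessages(library(fnirstrain))

qs <- read.delim("results/cohort/questionnaires.tsv")
iv <- read.delim("results/cohort/interventions.tsv")
dir.create("results", showWarnings = FALSE)

scales <- c("BDI", "SWE", "SCS", "SRQ")
qt <- rm_manova(qs, dv = scales, within = "time", between = "group")
cat("questionnaires, multivariate tests:\n")
print(qt$multivariate[, c("effect", "statistic", "F", "df1", "df2",
                          "p_raw", "effect_size")], digits = 3)
write.table(qt$multivariate, "results/questionnaire_multivariate.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

posthoc <- list()
for (sc in scales) {
  w <- reshape(qs[, c("subject", "time", sc)], direction = "wide",
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
posthoc$p_corr <- bh_adjust(posthoc$p_raw)  # one family of twelve
cat("\npost-hoc comparisons (BH-corrected):\n")
print(posthoc[, c("effect", "statistic", "df1", "p_raw", "p_corr",
                  "effect_size")], digits = 3)
write.table(posthoc, "results/questionnaire_posthoc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ivt <- rbind(
  chisq_tests(as.vector(table(factor(iv$session, levels = 1:8))),
              effect = "interventions across sessions"),
  chisq_tests(as.vector(table(factor(iv$phase, levels = 1:3))),
              effect = "interventions across phases"),
  chisq_tests(as.vector(table(iv$category)),
              effect = "intervention categories"),
  chisq_tests(table(iv$category, iv$phase), effect = "category x phase"))
cat("\nintervention chi-squared tests:\n")
print(ivt[, c("effect", "statistic", "df1", "p_raw")], digits = 4)
write.table(ivt, "results/intervention_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nphase shares (%):",
    round(100 * as.vector(table(iv$phase)) / nrow(iv), 1), "\n")
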