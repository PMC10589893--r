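#!/usr/bin/env Rscript
# Generate the synthetic study cohort at the default conditions
# (42 subjects x 8 sessions x 20+20 trials of 40 s, block-randomized per
# 10 trials) and write its components under results/cohort/.

suppressMessages(library(fnirstrain))

seed <- 1
cfg <- sim_config()
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

bundle <- simulate_cohort(cfg, seed = seed)

write_contrasts(bundle$contrasts, "results/cohort/contrasts.tsv",
                extra = sprintf("seed: %d", seed))
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
write_tsv(bundle$ratings, "results/cohort/ratings.tsv")
write_tsv(bundle$interventions, "results/cohort/interventions.tsv")
write_tsv(bundle$questionnaires, "results/cohort/questionnaires.tsv")
write_events(bundle$events[[1]], "results/cohort/events_s01_sess1.tsv")
jsonlite::write_json(
  list(seed = seed,
       contrast_session1 = as.list(cfg$contrast_session1),
       contrast_slope = as.list(cfg$contrast_slope),
       questionnaire_truth = bundle$ground_truth$questionnaires),
  "results/cohort/ground_truth.json", auto_unbox = TRUE, digits = NA)

cat("cohort:", cfg$n_subjects, "subjects x", cfg$n_sessions, "sessions;",
    nrow(bundle$contrasts), "contrast records,",
    nrow(bundle$ratings), "rated trials,",
    nrow(bundle$interventions), "intervention events\n")
cat("first session of subject 1:",
    sum(bundle$events[[1]]$trials$trial_type == "training"),
    "training +", sum(bundle$events[[1]]$trials$trial_type == "control"),
    "control trials\n")
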