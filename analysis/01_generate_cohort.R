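#!/usr/bin/env Rscript
# Generate the synthetic study cohorts: a "home" dataset (noisier, larger
# camera motion; one all-negative task per participant) and a smaller
# "homelab" supplement (cleaner recordings, same participants), then write
# the home dataset to disk in the standard layout and summarize what was
# produced.
#
# Outputs: results/dataset/ (frames, masks, annotations, manifest.json),
#          results/cohort_summary.csv

library(egohand)

seed <- 20260922L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

# Desk-scale study: 6 participants, 4 home tasks (one negative), 120-frame
# tasks keep this driver quick; the acceptance script uses the full 300.
home_spec <- cohort_spec(n_participants = 6, tasks_per_participant = 4,
                         frames_per_task = 120, seed = seed, env = "home")
homelab_spec <- cohort_spec(n_participants = 6, tasks_per_participant = 3,
                            frames_per_task = 120, seed = seed, env = "homelab")

home <- generate_cohort(home_spec)
homelab <- generate_cohort(homelab_spec)
study <- combine_datasets(home, homelab)

message(sprintf("cohort: %d participants, %d tasks (%d home / %d homelab)",
                nrow(study$profiles), nrow(study$manifest),
                sum(study$manifest$env == "home"),
                sum(study$manifest$env == "homelab")))
message(sprintf("realized interaction fraction (home, interaction tasks): %.2f",
                home$realized$interaction_fraction))
message(sprintf("realized manipulation fraction (home, bimanual interactions): %.2f",
                home$realized$manipulation_fraction))

write_dataset(home, file.path(out_dir, "dataset"))
message("home dataset written to ", file.path(out_dir, "dataset"))

summary_df <- merge(study$manifest,
                    study$profiles[, c("participant_id", "affected_side", "severity")],
                    by = "participant_id")
write.csv(summary_df, file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)
message("cohort summary written to ", file.path(out_dir, "cohort_summary.csv"))
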