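#!/usr/bin/env Rscript
# Step 1 — simulate the study material.
#
# Generates a synthetic normal cohort of preprocessed gray-matter maps
# (16^3 grid, 240 subjects, ages 68-72 so every patient has a large age- and
# sex-matched pool) plus four synthetic patients with 30% mesiotemporal
# gray-matter loss, and writes everything to disk as NIfTI volumes with a
# cohort CSV — the same on-disk layout a real preprocessed study would have.

suppressPackageStartupMessages(library(atrophynorm))

seed <- 20240101L
out_dir <- "results/cohort"
dir.create(file.path(out_dir, "volumes"), recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_cohort_spec(shape = c(16, 16, 16), voxel_size = c(2, 2, 2),
                              n_subjects = 240, age_range = c(68, 72),
                              sex_ratio = 0.5, seed = seed)
cohort <- generate_cohort(spec)

cohort$table$volume_ref <- file.path(out_dir, "volumes",
                                     paste0(cohort$table$subject_id, ".nii.gz"))
for (i in seq_len(nrow(cohort$table)))
  write_volume(cohort$volumes[[i]], cohort$table$volume_ref[i])
write_cohort_table(cohort$table, file.path(out_dir, "cohort.csv"))

# four patients, two per sex, bilateral mesiotemporal atrophy at 30% severity
masks <- default_mesiotemporal_masks(spec$shape, spec$voxel_size)
patients <- data.frame(subject_id = sprintf("AD%02d", 1:4), age = 70L,
                       sex = rep(c("female", "male"), each = 2),
                       cohort = "synthetic-ad", scanner = "synthetic",
                       volume_ref = file.path(out_dir, "volumes",
                                              sprintf("AD%02d.nii.gz", 1:4)),
                       stringsAsFactors = FALSE)
for (i in 1:4) {
  set.seed(seed + 1000L + i)
  vol <- generate_subject(spec, patients$age[i], patients$sex[i],
                          patients$subject_id[i])
  vol <- inject_atrophy(vol, masks$left, 0.3)
  vol <- inject_atrophy(vol, masks$right, 0.3)
  write_volume(vol, patients$volume_ref[i])
}
write_cohort_table(patients, file.path(out_dir, "patients.csv"))

message(sprintf("Wrote %d normal subjects and %d patients under %s",
                nrow(cohort$table), nrow(patients), out_dir))
message(sprintf("Matched pool for a 70-year-old female: %d subjects",
                nrow(match_subjects(cohort$table, 70, "female"))))
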