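#!/usr/bin/env Rscript
# Step 3 — knee detection on the saved curves.
#
# Re-reads the per-patient consistency-curve CSVs (demonstrating that the
# knee stage needs nothing but the curves), re-runs Kneedle-style knee
# detection, writes one knee JSON per patient, and plots all curves with
# their knees marked.

suppressPackageStartupMessages(library(atrophynorm))

in_dir <- "results/experiment"
fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

curve_files <- list.files(in_dir, pattern = "^curve_.*\\.csv$", full.names = TRUE)
stopifnot(length(curve_files) > 0)
curves <- lapply(curve_files, read_curve)
knees <- lapply(curves, find_knee)

for (i in seq_along(curves))
  write_knee_json(knees[[i]],
                  file.path(in_dir, paste0("knee_", curves[[i]]$patient_id, ".json")))

pdf(file.path(fig_dir, "consistency_curves.pdf"), width = 7, height = 5)
ylim <- c(0, max(vapply(curves, function(cv) max(cv$value), numeric(1))))
plot(NULL, xlim = range(curves[[1]]$n), ylim = ylim,
     xlab = "subjects in the normal template",
     ylab = "spatial mean of across-repeat z-score SD",
     main = "Consistency of atrophy estimates vs. template size")
cols <- seq_along(curves)
for (i in seq_along(curves)) {
  lines(curves[[i]]$n, curves[[i]]$value, col = cols[i])
  if (knees[[i]]$found)
    abline(v = knees[[i]]$n_at_knee, col = cols[i], lty = 3)
}
legend("topright", legend = vapply(curves, function(cv) cv$patient_id,
                                   character(1)), col = cols, lty = 1, bty = "n")
invisible(dev.off())

for (i in seq_along(curves))
  message(sprintf("%s: knee at %s subjects (distance %.3f)",
                  curves[[i]]$patient_id,
                  ifelse(knees[[i]]$found, knees[[i]]$n_at_knee, "none"),
                  knees[[i]]$distance))
found <- vapply(knees, function(k) k$found, logical(1))
message(sprintf("Max knee across patients: %d",
                max(vapply(knees[found], function(k) k$n_at_knee, integer(1)))))
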