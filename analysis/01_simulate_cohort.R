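#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: 15 participants, a 200-node SI hand
# sheet, four runs per task, active gain 1.5 vs passive 1, plus forward and
# backward travelling-wave localiser runs per participant. Everything below
# derives deterministically from the root seed, so later scripts regenerate
# the same cohort instead of reading these files back.

suppressMessages(library(somatomap))

cfg <- pipeline_config(seed = 42)
cohort <- simulate_cohort(cfg)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (pt in cohort) {
  write_activity_tsv(pt$active, file.path(out, paste0(pt$participant_id, "_active.tsv")))
  write_activity_tsv(pt$passive, file.path(out, paste0(pt$participant_id, "_passive.tsv")))
  write_localiser_tsv(pt$localiser_fwd, file.path(out, paste0(pt$participant_id, "_loc_fwd.tsv")))
  write_localiser_tsv(pt$localiser_bwd, file.path(out, paste0(pt$participant_id, "_loc_bwd.tsv")))
}
write.table(cohort[[1]]$sheet, file.path(out, "sheet.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

message("wrote ", length(cohort), " participants to ", out,
        " (", cfg$n_nodes, " nodes, ", cfg$n_runs, " runs/task)")
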