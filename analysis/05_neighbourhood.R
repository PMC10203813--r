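#!/usr/bin/env Rscript
# Neighbourhood-relationships analysis within the localiser-defined clusters:
# per-digit mean activity per cluster (shifted non-negative per participant),
# target-vs-neighbour and target-vs-non-neighbour selectivity ratios, the
# 2x2 repeated-measures ANOVA (neighbourhood x task), Wilcoxon follow-ups at
# the Bonferroni-adjusted alpha .0125, and the overall-activity comparison.

suppressMessages(library(somatomap))

cfg <- pipeline_config(seed = 42)
cohort <- simulate_cohort(cfg)
bank <- build_reference_bank(tr = 2, cycles = 5)

out <- "results/neighbourhood"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tables <- list(); sels <- list()
for (i in seq_along(cohort)) {
  pt <- cohort[[i]]
  ca <- assign_digits(pt$localiser_fwd, pt$localiser_bwd, bank, q = cfg$fdr_q)
  tb <- extract_cluster_activity(list(active = pt$active, passive = pt$passive), ca)
  long <- as.data.frame.table(tb$values, responseName = "activity")
  names(long)[1:3] <- c("task", "cluster", "digit")
  write.table(long, file.path(out, paste0(pt$participant_id, "_cluster_activity.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  tables[[i]] <- tb
  sels[[i]] <- selectivity_ratios(tb)
}

inf <- neighbourhood_inference(sels, activity_tables = tables)
hits <- Reduce(`+`, lapply(sels, `[[`, "hits"))

sel_df <- data.frame(
  participant = vapply(cohort, `[[`, "", "participant_id"),
  nb_active = vapply(sels, function(s) s$neighbour_diff[["active"]], 0),
  nb_passive = vapply(sels, function(s) s$neighbour_diff[["passive"]], 0),
  nn_active = vapply(sels, function(s) s$nonneighbour_diff[["active"]], 0),
  nn_passive = vapply(sels, function(s) s$nonneighbour_diff[["passive"]], 0))
write.csv(sel_df, file.path(out, "selectivity.csv"), row.names = FALSE)

jsonlite::write_json(
  list(anova = as.data.frame(inf$anova),
       wilcoxon = inf$wilcoxon, alpha_followup = inf$alpha_followup,
       shapiro_p = as.list(inf$shapiro),
       hits_of_75 = as.list(hits),
       overall_activity = list(t = unname(inf$overall_activity$statistic),
                               p = inf$overall_activity$p.value)),
  file.path(out, "neighbourhood_tests.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("selectivity hits: active %d/75, passive %d/75",
                hits["active"], hits["passive"]))
message(sprintf("ANOVA: neighbourhood F = %.1f (p = %.2g), task F = %.2f, interaction F = %.2f",
                inf$anova["neighbourhood", "F"], inf$anova["neighbourhood", "p"],
                inf$anova["task", "F"], inf$anova["neighbourhood_x_task", "F"]))
message(sprintf("overall activity active vs passive: t = %.2f, p = %.3g",
                inf$overall_activity$statistic, inf$overall_activity$p.value))
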