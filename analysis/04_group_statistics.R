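#!/usr/bin/env Rscript
# Stage 4 - group-level statistics and study-style report.
#
# Takes the per-animal vicinity proportions of stage 3 and the rendered
# per-animal study table of stage 2; applies the normality gate, compares
# the groups (Kruskal-Wallis + Dunn's, or ANOVA + Tukey when the gate
# allows), and summarises the headline proportions with per-animal
# mean +/- SEM.
#
# Outputs under results/04_report/: group_comparison.json,
# summary_proportions.csv, regression.json

library(plaqcluster)

out <- "results/04_report"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

per_animal <- read.csv("results/03_nullsim/per_animal.csv")
design <- read.csv("results/01_simulate/design.csv")
per_animal$group_label <-
  design$group_label[match(per_animal$animal_id, design$animal_id)]

cmpg <- suppressWarnings(
  compare_groups(per_animal, "observed", "group_label"))
message(sprintf("route: %s; %s = %.3f, p = %.3g", cmpg$route,
                cmpg$omnibus$method, cmpg$omnibus$statistic,
                cmpg$omnibus$p_value))
if (!is.null(cmpg$posthoc)) {
  message("post hoc comparisons:")
  print(cmpg$posthoc)
}
jsonlite::write_json(
  list(route = cmpg$route, omnibus = cmpg$omnibus, posthoc = cmpg$posthoc,
       groups = cmpg$groups),
  file.path(out, "group_comparison.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)

# proportions + regression from the rendered subset
tab <- read.csv("results/02_pipeline/study_table.csv")
summary_tab <- summarize_proportions(tab)
write.csv(summary_tab, file.path(out, "summary_proportions.csv"),
          row.names = FALSE)
overall <- summary_tab[summary_tab$group == "overall", ]
message("overall proportions (per-animal mean +/- SEM):")
for (r in seq_len(nrow(overall)))
  message(sprintf("  %-26s %5.1f%% +/- %s (n = %d animals)",
                  overall$quantity[r], 100 * overall$mean[r],
                  ifelse(is.na(overall$sem[r]), "NA",
                         sprintf("%.1f%%", 100 * overall$sem[r])),
                  overall$n_animals[r]))

records <- read.csv("results/02_pipeline/records.csv")
fit <- core_size_regression(records[!records$is_new, ])
jsonlite::write_json(fit[c("slope", "intercept", "r_squared", "p_value",
                           "n")],
                     file.path(out, "regression.json"), auto_unbox = TRUE,
                     digits = NA)
message(sprintf(
  "core-count vs size: slope %.1f um^2/core, R^2 = %.3f, p = %.2g, n = %d",
  fit$slope, fit$r_squared, fit$p_value, fit$n))
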