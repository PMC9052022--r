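#!/usr/bin/env Rscript
# Stage 3: immediate effects. Daily metrics are averaged over the 7 days
# before and the 7 days after each visit (visit day excluded; days with
# fewer than 1000 steps are missing; each window needs >= 4 valid days), and
# before/after are compared per metric with Wilcoxon signed-rank tests —
# for all visits and for complete visits only.

suppressPackageStartupMessages({
  library(modact)
  library(data.table)
})

daily <- validate_days(read_daily_csv("results/cohort/daily.csv"))
visits <- classify_completion(
  parse_events(read_events_csv("results/cohort/events.csv")))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
for (mid in unique(visits$module_id)) {
  mv <- visits[module_id == mid]
  for (scope in c("all", "completed")) {
    pairs <- build_before_after(mv, daily,
                                completed_only = scope == "completed")
    tab <- immediate_effect_table(pairs)
    fwrite(tab, sprintf("results/tables/immediate_%s_%s.csv", mid, scope))
    fwrite(pairs, sprintf("results/tables/pairs_%s_%s.csv", mid, scope))
    cat(sprintf("\n== %s module, %s visits (n pairs = %d) ==\n",
                mid, scope, attr(pairs, "n_pairs")))
    print(render_effect_table(tab))
  }
}
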