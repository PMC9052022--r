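#!/usr/bin/env Rscript
# Stage 4: sustained effects. For complete visits to the barriers module,
# the three active-minute metrics are summarised for the before-window and
# each of the 8 weeks after the visit (week k = days 7(k-1)+1 .. 7k), each
# week tested against the before-window with a signed-rank test.

suppressPackageStartupMessages({
  library(modact)
  library(data.table)
})

daily <- validate_days(read_daily_csv("results/cohort/daily.csv"))
visits <- classify_completion(
  parse_events(read_events_csv("results/cohort/events.csv")))

completed <- visits[module_id == "barriers" & complete == TRUE]
wk <- weekly_windows(completed, daily)
tab <- sustained_effect_table(wk)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
fwrite(tab, "results/tables/sustained_barriers.csv")

cat("Sustained effects, barriers module,", nrow(completed),
    "complete visits:\n")
print(render_effect_table(tab))
cat("\nWeeks flagged per metric (signed-rank vs before, alpha = .05):\n")
flagged <- tab[!is.na(p_value) & p_value < 0.05,
               .(weeks = paste(window, collapse = ", ")), by = metric]
print(flagged)
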