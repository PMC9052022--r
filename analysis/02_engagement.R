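#!/usr/bin/env Rscript
# Stage 2: reconstruct module visits from the log events, classify completion
# (a visit is complete if it lasted at least 33% of the module's estimated
# duration, or if its end event is missing), and summarise engagement:
# visitor proportions, visit and completion counts, first-visit delays.

suppressPackageStartupMessages({
  library(modact)
  library(data.table)
})

events <- read_events_csv("results/cohort/events.csv")
roster <- read_roster_csv("results/cohort/roster.csv")

visits <- classify_completion(parse_events(events), default_module_specs())
delays <- first_visit_delay(visits, roster)
stats <- user_statistics(visits, roster)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write_visits_csv(visits, "results/tables/visits.csv")
fwrite(stats, "results/tables/user_statistics.csv")
fwrite(delays$summary, "results/tables/first_visit_delays.csv")

cat("Engagement funnel:\n")
print(stats)
cat("\nFirst-visit delay (days after first login):\n")
print(delays$summary)
cat("\nVisits with a missing end event (classified complete):",
    sum(is.na(visits$duration_s)), "\n")
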