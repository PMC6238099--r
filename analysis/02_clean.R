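#!/usr/bin/env Rscript
# Step 2: parse the raw log against the menu catalog and apply the three
# exclusion rules (invalid/compound queries, successive duplicate menu
# selections, misspelled keywords). The cleaning report is a conservation
# ledger, checked here against the generator's injected-noise ground truth.

suppressMessages(library(m4rhfunnel))

log <- read_log("results/synthetic_log.csv")
cat("raw log:", nrow(log), "queries\n")

res <- clean(parse_events(log, m4rh_catalog()))
print(res$report)

write_log(res$log, "results/clean_log.csv")
write_cleaning_report(res$report, "results/cleaning_report.json")

truth <- read.csv("results/ground_truth_summary.csv")
stopifnot(
  res$report$removed_invalid == truth$injected_invalid,
  res$report$removed_successive_duplicates == truth$injected_duplicate,
  res$report$removed_misspelled_keyword == truth$injected_misspell
)
cat("ledger matches injected noise exactly; kept",
    res$report$kept, "queries from", res$report$kept_unique_users, "users\n")
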