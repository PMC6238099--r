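#!/usr/bin/env Rscript
# Step 1: generate a synthetic m4RH-style query log spanning the full
# Sep 2013 - Aug 2016 study window. The generator keeps the deployment's
# funnel probabilities, noise rates, promotion calendar and access-time
# profile, but runs at 12 new users/day instead of 381 so the whole workflow
# reruns in well under a minute; all downstream rates are arrival-rate-free.

suppressMessages(library(m4rhfunnel))
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = 20130901 %% 99991, base_arrival_rate = 12)
cat("simulating", format(cfg$window_start), "to", format(cfg$window_end),
    "at", cfg$base_arrival_rate, "new users/day ...\n")
sim <- simulate_log(cfg)

write_log(sim$log, "results/synthetic_log.csv")
tr <- sim$truth$users
truth_summary <- data.frame(
  n_users = nrow(tr),
  share_activated = mean(tr$stage != "initiated"),
  share_active = mean(tr$stage == "active"),
  share_return = mean(tr$is_return),
  injected_invalid = sim$truth$injected[["invalid"]],
  injected_duplicate = sim$truth$injected[["duplicate"]],
  injected_misspell = sim$truth$injected[["misspell"]]
)
write.csv(truth_summary, "results/ground_truth_summary.csv", row.names = FALSE)

cat(sprintf(
  "wrote %d raw queries from %d users (ground truth: %.1f%% ever activated, %.1f%% active, %.1f%% return)\n",
  nrow(sim$log), nrow(tr), 100 * truth_summary$share_activated,
  100 * truth_summary$share_active, 100 * truth_summary$share_return))
cat(sprintf("injected noise: %d invalid, %d successive duplicates, %d misspelled keywords\n",
            truth_summary$injected_invalid, truth_summary$injected_duplicate,
            truth_summary$injected_misspell))
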