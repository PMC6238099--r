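#!/usr/bin/env Rscript
# Step 4: interaction, loyalty, depth, temporal and environment indicators:
# monthly new/return/repeat users and acquisition, promotion association,
# time-of-day profiles, inter-query tempo, per-cohort menu depth shares,
# content queries per user-month, and the ward-lookup district distribution.

suppressMessages(library(m4rhfunnel))

catalog <- m4rh_catalog()
log <- read_log("results/clean_log.csv")
journeys <- build_journeys(parse_events(log, catalog), catalog)
win <- m4rh_window()
periods <- yearly_periods(win$start, win$end)

monthly <- monthly_engagement(journeys)
write.csv(monthly, "results/monthly_engagement.csv", row.names = FALSE)
cat("return users:", length(classify_return_users(journeys)), "of",
    nrow(journeys), "\n")

promo <- promotion_association(monthly, m4rh_promo_calendar())
print(as.data.frame(promo), row.names = FALSE)
write.csv(promo, "results/promotion.csv", row.names = FALSE)

tp3 <- temporal_profile(journey_events(journeys), 3)
write.csv(tp3, "results/temporal_3h.csv", row.names = FALSE)
write.csv(temporal_profile(journey_events(journeys), 1),
          "results/temporal_1h.csv", row.names = FALSE)
peaks <- tp3[tp3$peak, ]
cat(sprintf("peak access window: %02d:00-%02d:00 (%.1f%% of queries)\n",
            peaks$bin_start[1], peaks$bin_end[1], 100 * peaks$share[1]))

iq <- interquery_stats(journeys)
cat(sprintf("daily span %.1f min on average; %.1f min between consecutive queries\n",
            iq$mean_daily_span_min, iq$mean_gap_min))

depth <- depth_shares(journeys, catalog, periods)
write.csv(depth, "results/depth_shares.csv", row.names = FALSE)
top <- depth[depth$level == "submenu", ] |> (\(d) d[order(-d$share), ])()
cat("most-requested submenu by cohort-share:", top$label[1],
    sprintf("(%.2f%% in %s)\n", top$share[1], top$period[1]))

kpm <- keywords_per_month(journeys, periods)
write.csv(kpm, "results/keywords_per_month.csv", row.names = FALSE)
ovk <- kpm[kpm$period == "overall", ]
cat(sprintf("content queries per active user-month: mean %.2f (SD %.2f)\n",
            ovk$mean, ovk$sd))

wd <- ward_distribution(journeys, synthetic_ward_districts())
write.csv(wd$districts, "results/ward_distribution.csv", row.names = FALSE)
cat("ward lookups resolved to", nrow(wd$districts), "districts; top:",
    wd$districts$district[1], sprintf("(%.2f%%)\n", wd$districts$share[1]))
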