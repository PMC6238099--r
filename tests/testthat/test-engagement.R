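catg <- m4rh_catalog()

journeys_from <- function(user, when, text) {
  build_journeys(clean(mk_log(user, when, text))$log, catg)
}

test_that("return users need activity in two distinct calendar months", {
  j <- journeys_from(
    c("a", "a", "b", "b", "c"),
    c("2014-03-02 10:00:00", "2014-04-02 10:00:00",   # a: Mar + Apr
      "2014-03-05 10:00:00", "2014-03-28 10:00:00",   # b: Mar only
      "2014-03-09 10:00:00"),
    c("m4rh", "66", "m4rh", "66", "m4rh")
  )
  expect_equal(classify_return_users(j), "a")
  empty <- build_journeys(clean(mk_log(character(), character(), character()))$log, catg)
  expect_equal(classify_return_users(empty), character())
})

test_that("repeat users need >1 in-month query spanning distinct items", {
  j <- journeys_from(
    c("a", "a", "b", "b", "c"),
    c("2014-03-02 10:00:00", "2014-03-09 10:00:00",   # a: 66 then 61
      "2014-03-05 10:00:00", "2014-03-28 10:00:00",   # b: 66 twice
      "2014-03-09 10:00:00"),                         # c: single query
    c("66", "61", "66", "66", "66")
  )
  expect_equal(classify_repeat_users(j, "2014-03"), "a")
  # looser reading: any second in-month query qualifies
  expect_setequal(classify_repeat_users(j, "2014-03", require_distinct_items = FALSE),
                  c("a", "b"))
  # keyword + code counts as two distinct items
  j2 <- journeys_from(c("d", "d"),
                      c("2014-03-02 10:00:00", "2014-03-02 10:05:00"),
                      c("m4rh", "66"))
  expect_equal(classify_repeat_users(j2, "2014-03"), "d")
})

test_that("monthly engagement partitions active users into new and return", {
  j <- journeys_from(
    c("a", "a", "b", "c"),
    c("2014-03-02 10:00:00", "2014-04-02 10:00:00",
      "2014-04-05 10:00:00", "2014-03-09 10:00:00"),
    c("m4rh", "66", "m4rh", "66")
  )
  m <- monthly_engagement(j)
  mar <- m[m$month == "2014-03", ]; apr <- m[m$month == "2014-04", ]
  expect_equal(mar$new_users, 2); expect_equal(mar$return_users, 0)
  expect_equal(apr$new_users, 1); expect_equal(apr$return_users, 1)
  expect_equal(m$acquisition, m$new_users + m$return_users)
  expect_true(all(m$repeat_users <= m$acquisition))
})

test_that("temporal profile bins local hours and flags peaks", {
  log <- mk_log(rep("u", 4),
                c("2014-03-02 13:00:00", "2014-03-02 13:30:00",
                  "2014-03-02 13:45:00", "2014-03-02 02:00:00"),
                rep("66", 4))
  tp <- temporal_profile(log, 3)
  expect_equal(nrow(tp), 8)
  expect_equal(sum(tp$share), 1)
  b12 <- tp[tp$bin_start == 12, ]
  expect_equal(b12$share, 0.75)
  expect_true(b12$peak)

  single <- temporal_profile(mk_log("u", "2014-03-02 07:10:00", "66"), 1)
  expect_equal(single$share[single$bin_start == 7], 1)

  empty <- temporal_profile(mk_log(character(), character(), character()), 3)
  expect_true(all(!empty$peak))

  # concatenating two logs sums their bin counts
  l1 <- mk_log(rep("u", 3), sprintf("2014-03-02 09:%02d:00", 1:3), rep("66", 3))
  l2 <- mk_log(rep("v", 2), sprintf("2014-03-02 19:%02d:00", 1:2), rep("61", 2))
  both <- mk_log(c(rep("u", 3), rep("v", 2)),
                 c(sprintf("2014-03-02 09:%02d:00", 1:3),
                   sprintf("2014-03-02 19:%02d:00", 1:2)),
                 c(rep("66", 3), rep("61", 2)))
  expect_equal(temporal_profile(both, 3)$n,
               temporal_profile(l1, 3)$n + temporal_profile(l2, 3)$n)
})

test_that("uniform synthetic times give equal bin shares within binomial error", {
  set.seed(2)
  n <- 6000
  when <- as.POSIXct("2014-03-01 00:00:00", tz = TZ) + runif(n, 0, 24 * 3600 - 1)
  log <- parse_events(event_log(sprintf("u%d", 1:n), when, rep("66", n)), catg)
  tp <- temporal_profile(log, 3)
  p0 <- 1 / 8
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(tp$share - p0) < 4 * se))
})

test_that("interquery stats: spans and gaps per user-day", {
  j <- journeys_from(rep("u", 3),
                     c("2014-03-02 12:00:00", "2014-03-02 12:30:00",
                       "2014-03-02 13:04:00"),
                     c("m4rh", "66", "61"))
  s <- interquery_stats(j)
  expect_equal(s$mean_daily_span_min, 64)
  expect_equal(s$mean_gap_min, 32)

  # singleton day: span 0, no gaps
  j2 <- journeys_from("u", "2014-03-02 12:00:00", "66")
  s2 <- interquery_stats(j2)
  expect_equal(s2$mean_daily_span_min, 0)
  expect_true(is.na(s2$mean_gap_min))
  expect_equal(s2$n_gaps, 0)

  # two users with identical streams: pooled means unchanged
  j3 <- journeys_from(c(rep("u", 3), rep("v", 3)),
                      rep(c("2014-03-02 12:00:00", "2014-03-02 12:30:00",
                            "2014-03-02 13:04:00"), 2),
                      rep(c("m4rh", "66", "61"), 2))
  s3 <- interquery_stats(j3)
  expect_equal(s3$mean_daily_span_min, 64)
  expect_equal(s3$mean_gap_min, 32)
  # per-user variant agrees here by symmetry
  s3u <- interquery_stats(j3, per_user = TRUE)
  expect_equal(s3u$mean_gap_min, 32)
})

test_that("depth shares are cohort-based and date-gated", {
  # 4 users first seen in 2014; 2 of them request code 66
  j <- journeys_from(
    c("a", "b", "c", "d", "a"),
    c("2014-02-01 10:00:00", "2014-02-02 10:00:00", "2014-02-03 10:00:00",
      "2014-02-04 10:00:00", "2014-02-05 10:00:00"),
    c("66", "66", "61", "m4rh", "66")  # a requests 66 twice: counted once
  )
  ds <- depth_shares(j, catg, yearly_periods("2014-01-01", "2014-12-31"))
  row66 <- ds[ds$period == "2014" & ds$code == "66", ]
  expect_equal(row66$users, 2)
  expect_equal(row66$share, 50.00)
  # youth submenu not yet implemented in 2014: NA, not 0
  row77 <- ds[ds$period == "2014" & ds$code == "77", ]
  expect_true(is.na(row77$share))
  # never-requested active node: 0
  row88 <- ds[ds$period == "2014" & ds$code == "88", ]
  expect_equal(row88$share, 0)
  # numerators never exceed cohort size
  expect_true(all(ds$users <= 4, na.rm = TRUE))
})

test_that("keywords per month: mean and sample SD of content user-months", {
  # one active user with 3 content queries in Feb and 7 in Mar
  j <- journeys_from(
    rep("u", 10),
    c(sprintf("2014-02-0%d 10:00:00", 1:3), sprintf("2014-03-0%d 10:00:00", 1:7)),
    rep("61", 10)
  )
  k <- keywords_per_month(j, yearly_periods("2014-01-01", "2014-12-31"))
  ov <- k[k$period == "overall", ]
  expect_equal(ov$mean, 5.0)
  expect_equal(round(ov$sd, 2), 2.83)

  # single observation: SD undefined
  j2 <- journeys_from("u", "2014-02-01 10:00:00", "61")
  k2 <- keywords_per_month(j2, yearly_periods("2014-01-01", "2014-12-31"))
  expect_true(is.na(k2$sd[k2$period == "overall"]))

  # equal counts: SD 0
  j3 <- journeys_from(c("u", "v"),
                      c("2014-02-01 10:00:00", "2014-02-02 10:00:00"),
                      c("61", "62"))
  k3 <- keywords_per_month(j3, yearly_periods("2014-01-01", "2014-12-31"))
  expect_equal(k3$sd[k3$period == "overall"], 0)
})

test_that("ward distribution resolves prefixes to districts", {
  # counts mirroring the deployment's two largest districts
  j <- journeys_from(
    c("a", "b", "c", "c"),
    c("2014-02-01 10:00:00", "2014-02-02 10:00:00",
      "2014-02-03 10:00:00", "2014-02-03 10:05:00"),
    c("dar", "kino", "dodo", "zzz")
  )
  wd <- ward_distribution(j, synthetic_ward_districts())
  dar <- wd$districts[wd$districts$district == "Dar es Salaam", ]
  expect_equal(dar$n, 2)
  expect_equal(dar$share, rate(2, 3))
  expect_equal(wd$unresolved, 1)

  # no ward queries: empty distribution
  j2 <- journeys_from("u", "2014-02-01 10:00:00", "66")
  expect_equal(nrow(ward_distribution(j2, synthetic_ward_districts())$districts), 0)

  # single district: share 100
  j3 <- journeys_from(c("a", "b"),
                      c("2014-02-01 10:00:00", "2014-02-02 10:00:00"),
                      c("dar", "kino"))
  wd3 <- ward_distribution(j3, synthetic_ward_districts())
  expect_equal(wd3$districts$share, 100.00)
})

test_that("promotion association splits acquisition by flagged months", {
  monthly <- tibble::tibble(
    month = sprintf("2014-%02d", 1:12),
    new_users = c(84, rep(0, 10), 16),
    return_users = c(50, rep(0, 10), 50),
    repeat_users = 0L,
    acquisition = c(134, rep(0, 10), 66)
  )
  cal <- promotion_calendar("2014-01")
  pa <- promotion_association(monthly, cal)
  y <- pa[pa$year == "2014", ]
  expect_equal(y$new_share, 84.00)
  expect_equal(y$return_share, 50.00)

  # all new users in flagged months
  pa2 <- promotion_association(monthly, promotion_calendar(sprintf("2014-%02d", 1:12)))
  expect_equal(pa2$new_share[pa2$year == "2014"], 100.00)

  # no flagged months in the year: not applicable (and a warning for the
  # out-of-range flagged month)
  expect_warning(
    pa3 <- promotion_association(monthly, promotion_calendar("2013-01")),
    "outside the data range")
  expect_true(is.na(pa3$new_share[pa3$year == "2014"]))
})

test_that("monthly partition property holds on simulated data", {
  sim <- small_sim(seed = 17, months = 5, rate = 5)
  cleaned <- clean(parse_events(sim$log, catg))$log
  j <- build_journeys(cleaned, catg)
  m <- monthly_engagement(j)
  expect_equal(m$acquisition, m$new_users + m$return_users)
  expect_true(all(m$acquisition >= m$new_users))
  # per-month actives recomputed independently
  ev <- journey_events(j)
  act <- tapply(ev$user_id, ev$month, function(u) length(unique(u)))
  expect_equal(m$acquisition, as.integer(act[m$month]), ignore_attr = TRUE)
  # repeat users are a subset of that month's actives
  for (mo in m$month[1:2]) {
    rep_u <- classify_repeat_users(j, mo)
    expect_true(all(rep_u %in% ev$user_id[ev$month == mo]))
  }
})
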