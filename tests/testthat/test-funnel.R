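catg <- m4rh_catalog()

test_that("rate and churn_rate reproduce the deployment's printed values", {
  ref <- m4rh_reference_counts()
  expect_equal(rate(ref$activated_users, ref$new_users), 46.10)
  expect_equal(rate(ref$active_users, ref$activated_users), 89.58)
  expect_equal(rate(ref$active_users, ref$new_users), 41.30)
  expect_equal(churn_rate(ref$new_users, ref$activated_users), 53.90)
  expect_equal(churn_rate(ref$activated_users, ref$active_users), 10.42)
  expect_equal(rate(5, 5), 100.00)
  expect_equal(churn_rate(7, 7), 0.00)
  expect_error(rate(1, 0), "denominator")
  expect_error(churn_rate(5, 6), "inconsistent")
})

test_that("rounding is half-up to two decimals", {
  expect_equal(rate(1, 800), 0.13)       # 0.125 rounds up
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(2.674, 2), 2.67)
})

test_that("build_journeys opens a journey on any valid event", {
  log <- clean(mk_log(c("a", "a", "b"),
                      c("2014-01-05 10:00:00", "2014-01-06 10:00:00",
                        "2014-02-01 12:00:00"),
                      c("m4rh", "66", "61")))$log
  j <- build_journeys(log, catg)
  expect_equal(nrow(j), 2)
  expect_equal(sort(j$n_events), c(1, 2))
  # user b never texted the keyword: a bare content code opens a journey
  expect_equal(j$max_stage[j$user_id == "b"], "active")
  expect_equal(j$months_active[j$user_id == "a"][[1]], c("2014-01"))

  empty <- build_journeys(clean(mk_log(character(), character(), character()))$log, catg)
  expect_equal(nrow(empty), 0)
})

test_that("classify_stage follows the nested funnel definition", {
  ev <- function(texts) {
    mk_log(rep("u", length(texts)),
           sprintf("2014-03-02 10:%02d:00", seq_along(texts)), texts)
  }
  expect_equal(classify_stage(ev("m4rh"), catg), "initiated")
  expect_equal(classify_stage(ev(c("m4rh", "66")), catg), "activated")
  expect_equal(classify_stage(ev(c("m4rh", "66", "61")), catg), "active")
  # direct 2-step content access is active
  expect_equal(classify_stage(ev(c("m4rh", "61")), catg), "active")
  # ward lookup is a content-level act
  expect_equal(classify_stage(ev(c("m4rh", "99", "dar")), catg), "active")
  # unknown code errors with the offending code named
  bad <- ev("m4rh")
  bad$parsed_kind <- "menu_code"; bad$parsed_code <- "424242"
  expect_error(classify_stage(bad, catg), "424242")
})

test_that("funnel_summary computes per-period rates from first-seen cohorts", {
  # 10 journeys in one period: 6 activated of which 5 active
  users <- sprintf("u%02d", 1:10)
  texts <- c(rep(list("m4rh"), 4),
             rep(list(c("m4rh", "66")), 1),
             rep(list(c("m4rh", "66", "61")), 5))
  rows <- purrr::imap(texts, function(tx, i) {
    tibble::tibble(user = users[i],
                   when = sprintf("2014-02-%02d 10:0%d:00", i, seq_along(tx) - 1),
                   text = tx)
  }) |> dplyr::bind_rows()
  log <- clean(mk_log(rows$user, rows$when, rows$text))$log
  j <- build_journeys(log, catg)
  fs <- funnel_summary(j, yearly_periods("2014-01-01", "2014-12-31"))
  y <- fs[fs$period == "2014", ]
  expect_equal(y$new_users, 10)
  expect_equal(y$activated, 6)
  expect_equal(y$active, 5)
  expect_equal(y$activation_rate, 60.00)
  expect_equal(y$active_use_rate, 83.33)
  expect_equal(y$conversion_rate, 50.00)
  expect_equal(y$churn_step1, 40.00)
  expect_equal(y$churn_step2, 16.67)
  # overall row equals the single period here
  expect_equal(fs[fs$period == "overall", ]$new_users, 10)

  # empty period: counts 0, rates NA (undefined, not 0)
  p2 <- tibble::tibble(label = c("a", "b"),
                       start = as.Date(c("2014-01-01", "2015-01-01")),
                       end = as.Date(c("2014-12-31", "2015-12-31")))
  fs2 <- funnel_summary(j, p2)
  b <- fs2[fs2$period == "b", ]
  expect_equal(b$new_users, 0)
  expect_true(is.na(b$activation_rate))

  # overlapping periods are a configuration error
  p3 <- tibble::tibble(label = c("a", "b"),
                       start = as.Date(c("2014-01-01", "2014-06-01")),
                       end = as.Date(c("2014-12-31", "2015-12-31")))
  expect_error(funnel_summary(j, p3), "overlap")
})

test_that("all-active journeys give 100 everywhere", {
  log <- clean(mk_log(c("a", "b"), c("2014-01-05 10:00:00", "2014-01-06 10:00:00"),
                      c("61", "62")))$log
  fs <- funnel_summary(build_journeys(log, catg))
  expect_true(all(fs$activation_rate == 100))
  expect_true(all(fs$active_use_rate == 100))
  expect_true(all(fs$conversion_rate == 100))
})

test_that("funnel counts are monotone and rates complementary on simulated logs", {
  sim <- small_sim(seed = 314, months = 4, rate = 6)
  cleaned <- clean(parse_events(sim$log, catg))$log
  j <- build_journeys(cleaned, catg)
  fs <- funnel_summary(j)
  expect_true(all(fs$new_users >= fs$activated))
  expect_true(all(fs$activated >= fs$active))
  ok <- !is.na(fs$activation_rate)
  expect_true(all(abs(fs$activation_rate[ok] + fs$churn_step1[ok] - 100) <= 0.011))
  ok2 <- !is.na(fs$active_use_rate)
  expect_true(all(abs(fs$active_use_rate[ok2] + fs$churn_step2[ok2] - 100) <= 0.011))
})

test_that("funnel_summary matches the brute-force per-user oracle on small logs", {
  set.seed(99)
  for (i in 1:8) {
    log <- clean(random_log(n_users = 6, n_events = sample(10:50, 1)))$log
    if (nrow(log) == 0) next
    j <- build_journeys(log, catg)
    periods <- yearly_periods(min(as.Date(log$timestamp)), max(as.Date(log$timestamp)))
    fs <- funnel_summary(j, periods)
    oracle <- brute_force_funnel(log, catg, periods)
    per <- fs[fs$period != "overall", ]
    expect_equal(per$new_users, oracle$per_period$new_users)
    expect_equal(per$activated, oracle$per_period$activated)
    expect_equal(per$active, oracle$per_period$active)
    ov <- fs[fs$period == "overall", ]
    expect_equal(ov$new_users, unname(oracle$overall["new"]))
    expect_equal(ov$active, unname(oracle$overall["active"]))
  }
})
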