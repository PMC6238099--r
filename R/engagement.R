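#' Return users: active in two or more calendar months
#'
#' @param journeys a `user_journeys` object.
#' @return character vector of user ids with events in >= 2 distinct local
#'   calendar months.
#' @export
classify_return_users <- function(journeys) {
  journeys$user_id[lengths(journeys$months_active) >= 2]
}

#' Repeat users within one calendar month
#'
#' Users with more than one query in the month. Repetition of a single menu
#' item does not qualify: by default the user's in-month queries must span at
#' least two distinct items (distinct parsed codes, with a bare keyword
#' counting as its own item). Set `require_distinct_items = FALSE` for the
#' looser reading where any second query in the month qualifies.
#'
#' @param journeys a `user_journeys` object.
#' @param month month key `"YYYY-MM"` (or anything `format`-able to it).
#' @param require_distinct_items interpret the same-item exclusion strictly
#'   (default `TRUE`).
#' @return character vector of user ids.
#' @export
classify_repeat_users <- function(journeys, month, require_distinct_items = TRUE) {
  ev <- journey_events(journeys)
  if (nrow(ev) == 0) return(character())
  m <- ev[ev$month == as_month_key(month), ]
  item <- ifelse(is.na(m$parsed_code), m$parsed_kind, m$parsed_code)
  agg <- tibble::tibble(user_id = m$user_id, item = item) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(n = dplyr::n(), k = dplyr::n_distinct(.data$item),
                     .groups = "drop")
  if (require_distinct_items) agg$user_id[agg$n > 1 & agg$k >= 2]
  else agg$user_id[agg$n > 1]
}

as_month_key <- function(x) {
  if (is.character(x) && all(grepl("^\\d{4}-\\d{2}$", x))) return(x)
  format(as.Date(x), "%Y-%m")
}

#' Monthly engagement ledger: new, return, repeat, acquisition
#'
#' For every calendar month with activity: `new_users` (first seen that
#' month), `return_users` (active that month, first seen earlier),
#' `acquisition` = new + return = everyone active in the month, and
#' `repeat_users` (see [classify_repeat_users()]).
#'
#' @param journeys a `user_journeys` object.
#' @param require_distinct_items passed to [classify_repeat_users()].
#' @return a tibble with one row per month key.
#' @export
monthly_engagement <- function(journeys, require_distinct_items = TRUE) {
  ev <- journey_events(journeys)
  if (nrow(ev) == 0) {
    return(tibble::tibble(month = character(), new_users = integer(),
                          return_users = integer(), repeat_users = integer(),
                          acquisition = integer()))
  }
  first_month <- setNames(month_key(journeys$first_seen), journeys$user_id)
  active <- dplyr::distinct(ev, .data$month, .data$user_id)
  active$is_new <- first_month[active$user_id] == active$month
  out <- active |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(new_users = sum(.data$is_new),
                     return_users = sum(!.data$is_new),
                     acquisition = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$month)
  out$repeat_users <- vapply(out$month, function(m) {
    length(classify_repeat_users(journeys, m, require_distinct_items))
  }, integer(1))
  out[, c("month", "new_users", "return_users", "repeat_users", "acquisition")]
}

#' Time-of-day access profile
#'
#' Query counts by local hour-of-day bin, with shares over all queries and
#' the peak bin(s) flagged. 3-hour bins reproduce the overall access-time
#' figure of the deployment; 1-hour bins the by-year one.
#'
#' @param log a cleaned `event_log` (or the event table of a journeys
#'   object).
#' @param bin_hours bin width in hours; must divide 24.
#' @return a `temporal_profile` tibble: `bin_start`, `bin_end`, `n`, `share`,
#'   `peak`.
#' @export
temporal_profile <- function(log, bin_hours = 3) {
  stopifnot(bin_hours >= 1, 24 %% bin_hours == 0)
  starts <- seq(0, 24 - bin_hours, by = bin_hours)
  hrs <- lubridate::hour(lubridate::with_tz(log$timestamp, M4RH_TZ))
  bin <- findInterval(hrs, starts)
  n <- tabulate(bin, nbins = length(starts))
  total <- sum(n)
  out <- tibble::tibble(
    bin_start = starts, bin_end = starts + bin_hours, n = n,
    share = if (total > 0) n / total else rep(NA_real_, length(n)),
    peak = if (total > 0) n == max(n) else rep(FALSE, length(n))
  )
  class(out) <- c("temporal_profile", class(out))
  out
}

#' Inter-query durations
#'
#' Two interaction-tempo statistics over user-days (a user-day is one user's
#' queries within one local calendar day):
#' \describe{
#'   \item{mean_daily_span_min}{mean of first-to-last query spans; a
#'     single-query day has span 0 and is included.}
#'   \item{mean_gap_min}{mean duration between consecutive same-day queries;
#'     single-query days contribute no gaps.}
#' }
#' By default both means pool all user-days / query pairs; with
#' `per_user = TRUE` they are means of per-user means, the alternative
#' reading of "average duration between each query".
#'
#' @param journeys a `user_journeys` object.
#' @param per_user average within users first.
#' @return list with `mean_daily_span_min`, `mean_gap_min`, `n_user_days`,
#'   `n_gaps`.
#' @export
interquery_stats <- function(journeys, per_user = FALSE) {
  ev <- journey_events(journeys)
  if (nrow(ev) == 0) {
    return(list(mean_daily_span_min = NA_real_, mean_gap_min = NA_real_,
                n_user_days = 0L, n_gaps = 0L))
  }
  ev <- ev[order(ev$user_id, ev$timestamp), ]
  ev$day <- as.Date(ev$timestamp, tz = M4RH_TZ)
  per_day <- ev |>
    dplyr::group_by(.data$user_id, .data$day) |>
    dplyr::summarise(
      span = as.numeric(difftime(max(.data$timestamp), min(.data$timestamp),
                                 units = "mins")),
      gaps = list(as.numeric(diff(.data$timestamp), units = "mins")),
      .groups = "drop"
    )
  if (per_user) {
    by_user <- per_day |>
      dplyr::group_by(.data$user_id) |>
      dplyr::summarise(span = mean(.data$span),
                       gap = mean(unlist(.data$gaps)), .groups = "drop")
    list(mean_daily_span_min = mean(by_user$span),
         mean_gap_min = mean(by_user$gap, na.rm = TRUE),
         n_user_days = nrow(per_day),
         n_gaps = length(unlist(per_day$gaps)))
  } else {
    gaps <- unlist(per_day$gaps)
    list(mean_daily_span_min = mean(per_day$span),
         mean_gap_min = if (length(gaps) > 0) mean(gaps) else NA_real_,
         n_user_days = nrow(per_day), n_gaps = length(gaps))
  }
}

#' Per-cohort shares of users requesting each menu node
#'
#' For every submenu and content node: the number of unique users in each
#' first-seen cohort who ever requested the node, as a share of the cohort's
#' new-user count. Nodes not yet active in a period (e.g. menus introduced in
#' 2015, for a 2013 cohort) are reported `NA`, not 0.
#'
#' @param journeys a `user_journeys` object.
#' @param catalog the [menu_catalog].
#' @param periods period tibble; defaults to yearly periods over the data.
#' @return tibble: `period`, `code`, `label`, `level`, `users`, `share`.
#' @export
depth_shares <- function(journeys, catalog, periods = NULL) {
  ev <- journey_events(journeys)
  if (is.null(periods)) {
    rng <- range(as.Date(journeys$first_seen, tz = M4RH_TZ))
    periods <- yearly_periods(rng[1], rng[2])
  }
  check_periods(periods)
  cohort <- setNames(assign_period(as.Date(journeys$first_seen, tz = M4RH_TZ), periods),
                     journeys$user_id)
  nodes <- catalog$nodes[catalog$nodes$level %in% c("submenu", "content"), ]
  req <- ev[ev$parsed_kind == "menu_code", ]
  req$cohort <- cohort[req$user_id]
  req <- dplyr::distinct(req, .data$cohort, .data$parsed_code, .data$user_id)
  counts <- req |>
    dplyr::count(.data$cohort, .data$parsed_code, name = "users")

  cohort_sizes <- table(factor(cohort, levels = periods$label))
  grid <- tidyr::expand_grid(period = periods$label, code = nodes$code)
  grid <- dplyr::left_join(grid, nodes[, c("code", "label", "level", "active_from")],
                           by = "code")
  grid <- dplyr::left_join(
    grid, counts, by = c(period = "cohort", code = "parsed_code"))
  grid$users[is.na(grid$users)] <- 0L
  p_end <- setNames(periods$end, periods$label)
  inactive <- !is.na(grid$active_from) & grid$active_from > p_end[grid$period]
  size <- as.integer(cohort_sizes[grid$period])
  grid$share <- unname(ifelse(inactive | size == 0, NA_real_,
                              round_half_up(100 * grid$users / size, 2)))
  grid$users[inactive] <- NA_integer_
  grid[, c("period", "code", "label", "level", "users", "share")]
}

#' Content queries per user-month among active users
#'
#' The unit of observation is a (user, month) pair with at least one
#' content-level query, restricted to active users. Returns the mean and
#' sample SD of those per-user-month counts, per period (cohort of first
#' activity) and overall.
#'
#' @param journeys a `user_journeys` object.
#' @param periods period tibble; defaults to yearly periods over the data.
#' @return tibble: `period`, `n_user_months`, `mean`, `sd` (`NA` with < 2
#'   observations).
#' @export
keywords_per_month <- function(journeys, periods = NULL) {
  ev <- journey_events(journeys)
  if (is.null(periods)) {
    rng <- range(as.Date(journeys$first_seen, tz = M4RH_TZ))
    periods <- yearly_periods(rng[1], rng[2])
  }
  check_periods(periods)
  active_users <- journeys$user_id[journeys$max_stage == "active"]
  cohort <- setNames(assign_period(as.Date(journeys$first_seen, tz = M4RH_TZ), periods),
                     journeys$user_id)
  cv <- ev[ev$level == "content" & ev$user_id %in% active_users, ]
  obs <- cv |>
    dplyr::count(.data$user_id, .data$month, name = "n_content")
  obs$period <- cohort[obs$user_id]
  summarise_kpm <- function(x, label) {
    tibble::tibble(
      period = label, n_user_months = nrow(x),
      mean = if (nrow(x) > 0) mean(x$n_content) else NA_real_,
      sd = if (nrow(x) >= 2) sd(x$n_content) else NA_real_
    )
  }
  dplyr::bind_rows(
    purrr::map(periods$label,
               function(lb) summarise_kpm(obs[!is.na(obs$period) & obs$period == lb, ], lb)),
    summarise_kpm(obs, "overall")
  )
}

#' Ward-lookup distribution across districts
#'
#' Resolves ward-prefix queries to districts and counts unique
#' (user, district) requests — a user asking twice about the same district
#' counts once, matching "sum of unique requests for all wards per district".
#' Prefixes absent from the map are tallied under `unresolved`.
#'
#' @param journeys a `user_journeys` object.
#' @param district_map data frame with columns `prefix`, `district`.
#' @return list with `districts` (tibble `district`, `n`, `share` over
#'   resolved requests) and `unresolved` (count).
#' @export
ward_distribution <- function(journeys, district_map) {
  stopifnot(all(c("prefix", "district") %in% names(district_map)))
  ev <- journey_events(journeys)
  w <- ev[ev$parsed_kind == "ward_prefix", ]
  if (nrow(w) == 0) {
    return(list(districts = tibble::tibble(district = character(), n = integer(),
                                           share = numeric()),
                unresolved = 0L))
  }
  w$district <- district_map$district[match(w$parsed_code,
                                            tolower(district_map$prefix))]
  unresolved <- dplyr::n_distinct(w[is.na(w$district), c("user_id", "parsed_code")])
  res <- dplyr::distinct(w[!is.na(w$district), ], .data$user_id, .data$district)
  counts <- res |> dplyr::count(.data$district, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  total <- sum(counts$n)
  counts$share <- if (total > 0) rate(counts$n, total) else numeric(0)
  list(districts = counts, unresolved = unresolved)
}

#' Promotion calendar
#'
#' @param months character vector of `"YYYY-MM"` keys flagged as promotional.
#' @return a `promotion_calendar` object.
#' @export
promotion_calendar <- function(months) {
  stopifnot(all(grepl("^\\d{4}-\\d{2}$", months)))
  structure(sort(unique(months)), class = "promotion_calendar")
}

#' Default m4RH Tanzania promotion calendar
#'
#' The deployment ran mass-media promotion in 15 of the 36 study months:
#' 4 in 2013, 10 in 2014, 1 in 2015, none in 2016. The specific months within
#' each year are not on record; this default places them at September-December
#' 2013, January-October 2014 and June 2015.
#'
#' @return a `promotion_calendar`.
#' @export
m4rh_promo_calendar <- function() {
  promotion_calendar(c(
    sprintf("2013-%02d", 9:12),
    sprintf("2014-%02d", 1:10),
    "2015-06"
  ))
}

#' Share of users acquired during promotional months
#'
#' Per calendar year: the percentage of that year's new (and of its return)
#' users whose acquisition month was flagged promotional. Years with no
#' flagged months get `NA` (not applicable), mirroring how the deployment
#' reported 2016. A final `total` row pools all years.
#'
#' @param monthly output of [monthly_engagement()].
#' @param calendar a [promotion_calendar].
#' @return tibble: `year`, `promo_months`, `new_users_promo`, `new_users`,
#'   `new_share`, `return_users_promo`, `return_users`, `return_share`.
#' @export
promotion_association <- function(monthly, calendar) {
  cal <- unclass(calendar)
  outside <- setdiff(cal, monthly$month)
  if (length(outside) > 0) {
    warning("promotional month(s) outside the data range ignored: ",
            paste(outside, collapse = ", "), call. = FALSE)
  }
  m <- monthly
  m$year <- substr(m$month, 1, 4)
  m$promo <- m$month %in% cal
  one <- function(df, label, n_promo_months) {
    np <- sum(df$new_users[df$promo]); nt <- sum(df$new_users)
    rp <- sum(df$return_users[df$promo]); rt <- sum(df$return_users)
    tibble::tibble(
      year = label, promo_months = n_promo_months,
      new_users_promo = np, new_users = nt,
      new_share = if (n_promo_months > 0 && nt > 0) rate(np, nt) else NA_real_,
      return_users_promo = rp, return_users = rt,
      return_share = if (n_promo_months > 0 && rt > 0) rate(rp, rt) else NA_real_
    )
  }
  yrs <- sort(unique(m$year))
  rows <- purrr::map(yrs, function(y) {
    df <- m[m$year == y, ]
    one(df, y, sum(df$promo))
  })
  dplyr::bind_rows(rows, one(m, "total", sum(m$promo)))
}

#' Bundle of interaction indicators
#'
#' Combines the monthly new/return/repeat/acquisition ledger with pooled
#' interaction tempo: mean queries per user per 24 h (over user-days), mean
#' queries per user per month (over user-months), and mean new users per day
#' over the journeys' span. Per-user (mean-of-means) variants of the two
#' query intensities are included alongside the pooled ones, as the
#' definition admits both readings.
#'
#' @param journeys a `user_journeys` object.
#' @param require_distinct_items passed to [classify_repeat_users()].
#' @return list with elements `monthly` (tibble) and `interaction`
#'   (named list of means).
#' @export
engagement_summary <- function(journeys, require_distinct_items = TRUE) {
  ev <- journey_events(journeys)
  monthly <- monthly_engagement(journeys, require_distinct_items)
  if (nrow(ev) == 0) {
    return(list(monthly = monthly,
                interaction = list(queries_per_user_day = NA_real_,
                                   queries_per_user_day_user_mean = NA_real_,
                                   queries_per_user_month = NA_real_,
                                   queries_per_user_month_user_mean = NA_real_,
                                   new_users_per_day = NA_real_)))
  }
  ev$day <- as.Date(ev$timestamp, tz = M4RH_TZ)
  per_day <- dplyr::count(ev, .data$user_id, .data$day)
  per_month <- dplyr::count(ev, .data$user_id, .data$month)
  span_days <- as.integer(max(ev$day) - min(ev$day)) + 1L
  list(
    monthly = monthly,
    interaction = list(
      queries_per_user_day = mean(per_day$n),
      queries_per_user_day_user_mean =
        mean(tapply(per_day$n, per_day$user_id, mean)),
      queries_per_user_month = mean(per_month$n),
      queries_per_user_month_user_mean =
        mean(tapply(per_month$n, per_month$user_id, mean)),
      new_users_per_day = nrow(journeys) / span_days
    )
  )
}
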