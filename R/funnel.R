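#' Reconstruct per-user journeys from a cleaned log
#'
#' One journey per distinct subscriber. Any valid event opens a journey: a
#' user whose first message is a bare content code (a common pattern — users
#' who learned the codes re-entered without texting the keyword) is a journey
#' too. Each user's maximum funnel stage is derived from the deepest menu
#' level ever requested (see [classify_stage()]).
#'
#' @param log a cleaned, parsed `event_log`.
#' @param catalog the [menu_catalog] the codes refer to.
#' @return a `user_journeys` tibble, one row per user: `user_id`,
#'   `first_seen`, `n_events`, `max_stage` (`initiated` < `activated` <
#'   `active`), `months_active` (list of `"YYYY-MM"` keys). The event-level
#'   table (events with a `level` column) is kept in attribute `events`.
#' @export
build_journeys <- function(log, catalog) {
  ev <- tibble::as_tibble(log)[order(log$user_id, log$timestamp), ]
  ev$level <- event_level(ev, catalog)
  if (nrow(ev) == 0) {
    out <- tibble::tibble(user_id = character(),
                          first_seen = lubridate::as_datetime(character(), tz = M4RH_TZ),
                          n_events = integer(), max_stage = character(),
                          months_active = list())
    return(structure(out, events = ev, class = c("user_journeys", class(out))))
  }
  ev$month <- month_key(ev$timestamp)
  out <- ev |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      first_seen = min(.data$timestamp),
      n_events = dplyr::n(),
      max_stage = stage_from_levels(.data$level),
      months_active = list(sort(unique(.data$month))),
      .groups = "drop"
    )
  structure(out, events = ev, class = c("user_journeys", class(out)))
}

#' @export
print.user_journeys <- function(x, ...) {
  cat("<user_journeys> ", nrow(x), " users, ",
      nrow(journey_events(x)), " events\n", sep = "")
  NextMethod()
}

#' Event-level table behind a journeys object
#'
#' @param journeys a `user_journeys` object.
#' @return the cleaned event tibble with `level` and `month` columns.
#' @export
journey_events <- function(journeys) attr(journeys, "events")

# menu level of each event: keyword events sit at keyword level, ward
# prefixes are content-level requests (the clinic locator's final step), menu
# codes take their catalog level.
event_level <- function(events, catalog) {
  lvl <- rep(NA_character_, nrow(events))
  lvl[events$parsed_kind == "keyword"] <- "keyword"
  lvl[events$parsed_kind == "misspelled_keyword"] <- "keyword"
  lvl[events$parsed_kind == "ward_prefix"] <- "content"
  is_code <- events$parsed_kind == "menu_code"
  code_lvl <- catalog_level(catalog, events$parsed_code[is_code])
  if (any(is.na(code_lvl))) {
    bad <- unique(events$parsed_code[is_code][is.na(code_lvl)])
    stop("code(s) not in catalog: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  lvl[is_code] <- code_lvl
  lvl
}

stage_from_levels <- function(levels) {
  if (any(levels == "content", na.rm = TRUE)) "active"
  else if (any(levels == "submenu", na.rm = TRUE)) "activated"
  else "initiated"
}

#' Maximum funnel stage of one journey
#'
#' `active` if any event requests content (a content code or a ward prefix —
#' including the direct 2-step path where a user enters a content code
#' straight after the welcome menu); otherwise `activated` if any event
#' requests a submenu; otherwise `initiated`. Stages nest: an active user
#' counts as activated in every funnel denominator.
#'
#' @param events event tibble for one user (needs `parsed_kind`,
#'   `parsed_code`).
#' @param catalog the [menu_catalog].
#' @return one of `"initiated"`, `"activated"`, `"active"`.
#' @export
classify_stage <- function(events, catalog) {
  stopifnot(nrow(events) > 0)
  stage_from_levels(event_level(events, catalog))
}

#' Yearly analysis periods clipped to a study window
#'
#' @param start,end study window (`Date`).
#' @return a tibble of periods: `label`, `start`, `end` (inclusive).
#' @export
yearly_periods <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  yrs <- seq(lubridate::year(start), lubridate::year(end))
  tibble::tibble(
    label = as.character(yrs),
    start = pmax(as.Date(paste0(yrs, "-01-01")), start),
    end = pmin(as.Date(paste0(yrs, "-12-31")), end)
  )
}

#' The m4RH Tanzania study window
#'
#' September 2013 through August 2016 (36 months), the period the
#' deployment's engagement indicators cover.
#'
#' @return list with `start` and `end` dates.
#' @export
m4rh_window <- function() {
  list(start = as.Date("2013-09-01"), end = as.Date("2016-08-31"))
}

check_periods <- function(periods) {
  stopifnot(all(c("label", "start", "end") %in% names(periods)))
  p <- periods[order(periods$start), ]
  if (any(p$end < p$start)) stop("period end precedes start", call. = FALSE)
  if (nrow(p) > 1 && any(p$start[-1] <= p$end[-nrow(p)])) {
    stop("periods overlap", call. = FALSE)
  }
  invisible(periods)
}

assign_period <- function(dates, periods) {
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  for (i in seq_len(nrow(periods))) {
    hit <- dates >= periods$start[i] & dates <= periods$end[i]
    out[hit] <- periods$label[i]
  }
  out
}

#' Per-period conversion-funnel summary
#'
#' Users enter the cohort of the period containing their first event (a user
#' is "new" exactly once); all later activity attributes depth to that
#' cohort. For each period and overall:
#' \describe{
#'   \item{activation_rate}{activated / new users x 100 — share who navigated
#'     from the welcome menu into a submenu.}
#'   \item{active_use_rate}{active / activated x 100 — share of navigators
#'     who went on to request content.}
#'   \item{conversion_rate}{active / new users x 100.}
#'   \item{churn_step1, churn_step2}{the complements: users lost at each
#'     step.}
#' }
#' Rates are `NA` (not 0) where the denominator is empty.
#'
#' @param journeys a `user_journeys` object.
#' @param periods period tibble (`label`, `start`, `end`), non-overlapping;
#'   default yearly periods spanning the journeys.
#' @return a `funnel_summary` tibble, one row per period plus `"overall"`.
#' @export
funnel_summary <- function(journeys, periods = NULL) {
  if (is.null(periods)) {
    if (nrow(journeys) == 0) stop("no journeys and no periods given", call. = FALSE)
    rng <- range(as.Date(journeys$first_seen, tz = M4RH_TZ))
    periods <- yearly_periods(rng[1], rng[2])
  }
  check_periods(periods)
  j <- tibble::as_tibble(journeys)
  j$period <- assign_period(as.Date(j$first_seen, tz = M4RH_TZ), periods)

  one <- function(df, label) {
    n_new <- nrow(df)
    n_act <- sum(df$max_stage %in% c("activated", "active"))
    n_acv <- sum(df$max_stage == "active")
    tibble::tibble(
      period = label, new_users = n_new, activated = n_act, active = n_acv,
      activation_rate = if (n_new > 0) rate(n_act, n_new) else NA_real_,
      active_use_rate = if (n_act > 0) rate(n_acv, n_act) else NA_real_,
      conversion_rate = if (n_new > 0) rate(n_acv, n_new) else NA_real_,
      churn_step1 = if (n_new > 0) churn_rate(n_new, n_act) else NA_real_,
      churn_step2 = if (n_act > 0) churn_rate(n_act, n_acv) else NA_real_
    )
  }
  rows <- purrr::map(periods$label,
                     function(lb) one(j[!is.na(j$period) & j$period == lb, ], lb))
  out <- dplyr::bind_rows(rows, one(j[!is.na(j$period), ], "overall"))
  class(out) <- c("funnel_summary", class(out))
  out
}
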