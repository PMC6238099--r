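#' Published headline counts of the m4RH Tanzania deployment
#'
#' The unique-user and query counts the deployment reported for September
#' 2013 - August 2016, usable as worked-example inputs to [rate()] and
#' [churn_rate()] (the raw subscriber logs themselves are not public).
#'
#' @return a named list of counts: raw and cleaned query totals, the removal
#'   ledger, funnel-stage user counts overall and per calendar year, and the
#'   promotion-month acquisition counts for 2014.
#' @export
m4rh_reference_counts <- function() {
  list(
    raw_queries = 4112460,
    removed_invalid = 35978,
    removed_successive_duplicates = 402780,
    removed_misspelled_keyword = 5663,
    analysis_queries = 3673702,
    new_users = 409768,
    activated_users = 188904,
    active_users = 169218,
    return_users = 150915,
    repeat_users = 278088,
    clinic_requesters = 23236,
    ward_resolved = 7737,
    ward_dar_es_salaam = 3939,
    yearly = tibble::tibble(
      year = c("2013", "2014", "2015", "2016"),
      new_users = c(43746, 116654, 151903, 97465),
      activated = c(11470, 34830, 77839, 64765),
      active = c(11246, 33551, 67725, 56696)
    ),
    promo_2014 = list(new_users_promo = 99012, new_users = 116654,
                      return_users_promo = 31084, return_users = 36887)
  )
}

#' Pipeline configuration
#'
#' @param log_path raw log CSV.
#' @param out_dir output directory (created if absent).
#' @param catalog_path YAML menu catalog (default the bundled one).
#' @param district_map_path ward-prefix map CSV (default the bundled
#'   synthetic one).
#' @param promo_calendar a [promotion_calendar].
#' @param periods period tibble, or `NULL` for yearly periods over the data.
#' @param require_distinct_items repeat-user interpretation flag.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(log_path, out_dir,
                            catalog_path = NULL, district_map_path = NULL,
                            promo_calendar = m4rh_promo_calendar(),
                            periods = NULL,
                            require_distinct_items = TRUE) {
  structure(list(log_path = log_path, out_dir = out_dir,
                 catalog_path = catalog_path,
                 district_map_path = district_map_path,
                 promo_calendar = promo_calendar, periods = periods,
                 require_distinct_items = require_distinct_items),
            class = "pipeline_config")
}

#' Run the full clean / funnel / engagement pipeline
#'
#' Reads the raw log, parses and cleans it, reconstructs journeys, and
#' writes a deterministic report bundle to `out_dir`:
#' `clean.csv` (cleaned log), `cleaning_report.json`, `funnel.csv`,
#' `monthly_engagement.csv`, `depth_shares.csv`, `keywords_per_month.csv`,
#' `ward_distribution.csv`, `promotion.csv`, `temporal_3h.csv`,
#' `temporal_1h.csv`, and `metrics.json` (a machine-readable bundle every
#' table number can be re-derived from). Rerunning on the same inputs gives
#' byte-identical files.
#'
#' @param config a [pipeline_config].
#' @return (invisibly) a list with all computed objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$log_path)) {
    stop("log not found: ", config$log_path, call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- if (is.null(config$catalog_path)) m4rh_catalog()
             else read_catalog(config$catalog_path)
  district_map <- if (is.null(config$district_map_path)) synthetic_ward_districts()
                  else readr::read_csv(config$district_map_path, col_types = "cc",
                                       progress = FALSE)

  log <- read_log(config$log_path)
  cleaned <- clean(parse_events(log, catalog))
  if (cleaned$report$kept == 0) {
    warning("cleaned log is empty; emitting empty tables", call. = FALSE)
  }
  journeys <- build_journeys(cleaned$log, catalog)
  periods <- config$periods
  if (is.null(periods) && nrow(journeys) > 0) {
    rng <- range(as.Date(journeys$first_seen, tz = M4RH_TZ))
    periods <- yearly_periods(rng[1], rng[2])
  }

  funnel <- if (nrow(journeys) > 0) funnel_summary(journeys, periods) else NULL
  monthly <- monthly_engagement(journeys, config$require_distinct_items)
  depth <- if (nrow(journeys) > 0) depth_shares(journeys, catalog, periods) else NULL
  kpm <- if (nrow(journeys) > 0) keywords_per_month(journeys, periods) else NULL
  wards <- ward_distribution(journeys, district_map)
  promo <- if (nrow(monthly) > 0)
    promotion_association(monthly, config$promo_calendar) else NULL
  tp3 <- temporal_profile(cleaned$log, 3)
  tp1 <- temporal_profile(cleaned$log, 1)
  iq <- interquery_stats(journeys)
  eng <- engagement_summary(journeys, config$require_distinct_items)

  out <- function(name) file.path(config$out_dir, name)
  write_log(cleaned$log, out("clean.csv"))
  write_cleaning_report(cleaned$report, out("cleaning_report.json"))
  wr <- function(x, name) if (!is.null(x)) readr::write_csv(x, out(name), progress = FALSE)
  wr(funnel, "funnel.csv")
  wr(monthly, "monthly_engagement.csv")
  wr(depth, "depth_shares.csv")
  wr(kpm, "keywords_per_month.csv")
  wr(wards$districts, "ward_distribution.csv")
  wr(promo, "promotion.csv")
  wr(tibble::as_tibble(tp3), "temporal_3h.csv")
  wr(tibble::as_tibble(tp1), "temporal_1h.csv")

  metrics <- list(
    cleaning = unclass(cleaned$report),
    funnel = funnel,
    interquery = iq,
    interaction = eng$interaction,
    ward_unresolved = wards$unresolved
  )
  jsonlite::write_json(metrics, out("metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", POSIXt = "ISO8601")

  invisible(list(log = log, cleaned = cleaned, journeys = journeys,
                 funnel = funnel, monthly = monthly, depth = depth,
                 keywords_per_month = kpm, wards = wards, promotion = promo,
                 temporal_3h = tp3, temporal_1h = tp1,
                 interquery = iq, engagement = eng))
}
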