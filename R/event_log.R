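#' Column mapping and timestamp format for a raw SMS log
#'
#' The canonical dialect is a comma-separated file with header
#' `user_id,timestamp,text` and ISO-8601 timestamps interpreted in
#' Africa/Dar_es_Salaam local time (the deployment timezone; all hour-of-day
#' and calendar-month results are local).
#'
#' @param user,timestamp,text column names in the source file.
#' @param tz timezone the timestamps are interpreted in.
#' @return a `log_dialect` list.
#' @export
log_dialect <- function(user = "user_id", timestamp = "timestamp",
                        text = "text", tz = M4RH_TZ) {
  structure(list(user = user, timestamp = timestamp, text = text, tz = tz),
            class = "log_dialect")
}

new_event_log <- function(events, provenance = list()) {
  events <- tibble::as_tibble(events)
  structure(events, provenance = provenance,
            class = c("event_log", class(events)))
}

#' Build an event log from vectors
#'
#' Convenience constructor used by the simulator and in tests. Events keep
#' file (input) order; `parsed_kind`/`parsed_code` columns are added by
#' [parse_events()].
#'
#' @param user_id character vector of opaque subscriber identifiers.
#' @param timestamp POSIXct vector (converted to Africa/Dar_es_Salaam).
#' @param text verbatim message bodies.
#' @return an `event_log` tibble.
#' @export
event_log <- function(user_id = character(), timestamp = as.POSIXct(character()),
                      text = character()) {
  stopifnot(length(user_id) == length(timestamp),
            length(user_id) == length(text))
  if (length(user_id) > 0 && any(is.na(user_id) | user_id == "")) {
    stop("user_id must be non-empty", call. = FALSE)
  }
  new_event_log(
    tibble::tibble(
      user_id = as.character(user_id),
      timestamp = lubridate::with_tz(timestamp, M4RH_TZ),
      text = as.character(text)
    ),
    provenance = list(source = "in-memory", n_input_rows = length(user_id),
                      n_rejected = 0L)
  )
}

#' Read a raw SMS query log
#'
#' Reads a delimited log with one row per inbound message. Rows whose
#' timestamp cannot be parsed or whose user id is empty are counted as
#' rejected (reported in the provenance attribute), never silently dropped.
#'
#' @param path path to a delimited text file.
#' @param dialect a [log_dialect] naming the user/timestamp/text columns.
#' @param delim field delimiter.
#' @return an `event_log` tibble with attribute `provenance`
#'   (`source`, `n_input_rows`, `n_rejected`).
#' @export
read_log <- function(path, dialect = log_dialect(), delim = ",") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  needed <- c(dialect$user, dialect$timestamp, dialect$text)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("log is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- suppressWarnings(
    lubridate::parse_date_time(raw[[dialect$timestamp]],
                               orders = c("Ymd HMS", "Ymd HM"),
                               tz = dialect$tz, quiet = TRUE)
  )
  ok <- !is.na(ts) & !is.na(raw[[dialect$user]]) & raw[[dialect$user]] != ""
  # a lone bad row is recorded as rejected; a multi-row file with nothing
  # parseable points at a wrong dialect and is a hard error
  if (nrow(raw) > 1 && !any(ok)) {
    stop("no parseable rows in '", path, "' (", nrow(raw), " input rows)",
         call. = FALSE)
  }
  new_event_log(
    tibble::tibble(
      user_id = raw[[dialect$user]][ok],
      timestamp = ts[ok],
      text = raw[[dialect$text]][ok] %||% ""
    ),
    provenance = list(source = path, n_input_rows = nrow(raw),
                      n_rejected = sum(!ok))
  )
}

#' Write an event log
#'
#' Writes the canonical comma-separated dialect (`user_id,timestamp,text`,
#' ISO-8601 local timestamps, UTF-8). `read_log(write_log(x))` reproduces the
#' events exactly.
#'
#' @param log an `event_log`.
#' @param path output path.
#' @return (invisibly) the number of data rows written.
#' @export
write_log <- function(log, path) {
  out <- tibble::tibble(
    user_id = log$user_id,
    timestamp = format(log$timestamp, "%Y-%m-%dT%H:%M:%S", tz = M4RH_TZ),
    text = log$text
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(nrow(out))
}

#' Classify one query text against the menu catalog
#'
#' Classification is case-insensitive and whitespace-trimmed and is total:
#' every text gets exactly one kind.
#' \itemize{
#'   \item the bare canonical keyword -> `keyword`;
#'   \item a listed misspelling (e.g. `mr4h`) -> `misspelled_keyword`;
#'   \item a code of a submenu/content node active on `query_date` ->
#'     `menu_code` (with the normalized code);
#'   \item a bare 3-4 letter alphabetic token (a ward-name prefix for the
#'     clinic locator) -> `ward_prefix`;
#'   \item keyword plus a code in one message (e.g. `"m4RH 66"`) ->
#'     `compound`: the production system answered these with nothing, so
#'     cleaning counts them with invalid;
#'   \item anything else -> `invalid`.
#' }
#' Codes of menus introduced later than `query_date` (About family planning
#' and Youth, added in 2015) classify as `invalid`, mirroring the live system.
#'
#' @param raw_text character vector of message bodies.
#' @param catalog a [menu_catalog].
#' @param query_date `Date` (scalar or per-message) the query was sent.
#' @return a tibble with columns `parsed_kind` and `parsed_code`
#'   (`NA` unless the kind is `menu_code` or `ward_prefix`).
#' @export
parse_query_text <- function(raw_text, catalog, query_date) {
  txt <- tolower(stringr::str_squish(as.character(raw_text)))
  query_date <- as.Date(query_date)
  if (length(query_date) == 1) query_date <- rep(query_date, length(txt))
  stopifnot(length(query_date) == length(txt))

  kind <- rep("invalid", length(txt))
  code <- rep(NA_character_, length(txt))

  is_keyword <- txt == catalog$keyword
  is_misspelled <- txt %in% catalog$misspellings

  # menu codes, date-gated per node
  nodes <- catalog$nodes[catalog$nodes$level %in% c("submenu", "content"), ]
  idx <- match(txt, nodes$code)
  node_active <- !is.na(idx) &
    (is.na(nodes$active_from[idx]) | nodes$active_from[idx] <= query_date)
  is_code <- !is.na(idx) & node_active

  # ward prefix: bare 3-4 letter token (not the keyword or a misspelling)
  is_ward <- stringr::str_detect(txt, "^[a-z]{3,4}$") & !is_keyword & !is_misspelled

  # keyword + anything else in one message
  multi <- stringr::str_detect(txt, "\\s")
  kw_rx <- paste0("(^|\\s)(", paste(c(catalog$keyword, catalog$misspellings),
                                    collapse = "|"), ")($|\\s)")
  is_compound <- multi & stringr::str_detect(txt, kw_rx)

  kind[is_ward] <- "ward_prefix"
  code[is_ward] <- txt[is_ward]
  kind[is_code] <- "menu_code"
  code[is_code] <- txt[is_code]
  kind[is_compound] <- "compound"
  code[is_compound] <- NA_character_
  kind[is_misspelled] <- "misspelled_keyword"
  kind[is_keyword] <- "keyword"

  tibble::tibble(parsed_kind = kind, parsed_code = code)
}

#' Parse every event in a log
#'
#' Adds `parsed_kind` and `parsed_code` columns (see [parse_query_text()]),
#' using each event's own local date for catalog date-gating.
#'
#' @param log an `event_log`.
#' @param catalog a [menu_catalog].
#' @return the log with parse columns added.
#' @export
parse_events <- function(log, catalog) {
  parsed <- parse_query_text(log$text, catalog,
                             as.Date(log$timestamp, tz = M4RH_TZ))
  log$parsed_kind <- parsed$parsed_kind
  log$parsed_code <- parsed$parsed_code
  log
}

#' @export
print.event_log <- function(x, ...) {
  p <- attr(x, "provenance")
  cat("<event_log> ", nrow(x), " events, ",
      dplyr::n_distinct(x$user_id), " users",
      if (!is.null(p$n_rejected) && p$n_rejected > 0)
        paste0(" (", p$n_rejected, " rejected rows at read)"),
      "\n", sep = "")
  NextMethod()
}
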