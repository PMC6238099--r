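#' Collapse successive duplicate menu selections
#'
#' Within each user's time-ordered stream, an event carrying a parsed code
#' (menu code or ward prefix) is removed when the immediately preceding kept
#' event has the same parsed code on the same local calendar day; the first
#' occurrence is always kept. Events without a code (keyword, misspelled
#' keyword, invalid) are never collapsed — they are not menu selections — and
#' an interleaved keyword breaks a run. Different users never interact, and a
#' day boundary resets the rule so genuine next-day re-visits survive.
#'
#' @param log a parsed `event_log` (see [parse_events()]).
#' @return a list with elements `log` (the collapsed log) and `removed`
#'   (number of events removed).
#' @export
collapse_successive_duplicates <- function(log) {
  if (nrow(log) == 0) return(list(log = log, removed = 0L))
  ord <- order(log$user_id, log$timestamp)
  x <- log[ord, ]
  day <- as.Date(x$timestamp, tz = M4RH_TZ)
  prev_same_user <- c(FALSE, x$user_id[-1] == x$user_id[-nrow(x)])
  prev_code <- c(NA_character_, x$parsed_code[-nrow(x)])
  prev_day <- c(as.Date(NA), day[-nrow(x)])
  dup <- prev_same_user &
    !is.na(x$parsed_code) & !is.na(prev_code) &
    x$parsed_code == prev_code & day == prev_day
  # runs of identical codes: every element after the first in a run follows a
  # kept-or-removed twin; with lag-1 comparison all but the first are flagged,
  # which is exactly "previous *kept* event" because removing the middle of a
  # run still leaves an identical kept predecessor.
  kept <- x[!dup, ]
  keep_ord <- ord[!dup]
  out <- log[sort(keep_ord), ]  # restore file order
  list(log = new_event_log(out, attr(log, "provenance")), removed = sum(dup))
}

#' Clean a parsed query log
#'
#' Applies the three exclusion rules, in a fixed documented order:
#' \enumerate{
#'   \item invalid queries — unrecognized text/codes and compound messages
#'     like `"m4RH 66"` (which the live system answered with nothing);
#'   \item duplicated menu selections sent in succession, judged on the
#'     stream left after step 1 (see [collapse_successive_duplicates()]);
#'   \item misspelled service keywords (`mr4h`, `m4hr`, `mrh4`, `mfrh`) —
#'     removed, not corrected.
#' }
#' The returned report is a conservation ledger:
#' `raw_total = kept + removed_invalid + removed_successive_duplicates +
#' removed_misspelled_keyword` always holds.
#'
#' @param log a parsed `event_log`.
#' @return a list with elements `log` (cleaned) and `report` (a
#'   `cleaning_report`: `raw_total`, `removed_invalid`,
#'   `removed_successive_duplicates`, `removed_misspelled_keyword`, `kept`,
#'   `kept_unique_users`).
#' @export
clean <- function(log) {
  if (is.null(log$parsed_kind)) {
    stop("log must be parsed first; see parse_events()", call. = FALSE)
  }
  raw_total <- nrow(log)
  bad <- log$parsed_kind %in% c("invalid", "compound")
  step1 <- new_event_log(log[!bad, ], attr(log, "provenance"))

  dedup <- collapse_successive_duplicates(step1)
  step2 <- dedup$log

  miss <- step2$parsed_kind == "misspelled_keyword"
  kept <- new_event_log(step2[!miss, ], attr(log, "provenance"))

  report <- structure(
    list(
      raw_total = raw_total,
      removed_invalid = sum(bad),
      removed_successive_duplicates = dedup$removed,
      removed_misspelled_keyword = sum(miss),
      kept = nrow(kept),
      kept_unique_users = dplyr::n_distinct(kept$user_id)
    ),
    class = "cleaning_report"
  )
  stopifnot(report$raw_total ==
              report$kept + report$removed_invalid +
              report$removed_successive_duplicates +
              report$removed_misspelled_keyword)
  list(log = kept, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n",
      sprintf("  raw queries:             %d\n", x$raw_total),
      sprintf("  removed invalid/compound:%d\n", x$removed_invalid),
      sprintf("  removed successive dups: %d\n", x$removed_successive_duplicates),
      sprintf("  removed misspelled kw:   %d\n", x$removed_misspelled_keyword),
      sprintf("  kept:                    %d (%d unique users)\n",
              x$kept, x$kept_unique_users), sep = "")
  invisible(x)
}

#' Serialize a cleaning report to JSON
#'
#' @param report a `cleaning_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
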