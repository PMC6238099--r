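# Shared fixtures: tiny logs built in code, a random-log generator for
# property tests, and an independent brute-force funnel oracle.

TZ <- "Africa/Dar_es_Salaam"

ts_at <- function(...) as.POSIXct(c(...), tz = TZ)

# build a parsed log from (user, timestamp-string, text) triples
mk_log <- function(user, when, text, catalog = m4rh_catalog()) {
  log <- event_log(user, ts_at(when), text)
  parse_events(log, catalog)
}

# random raw log mixing valid codes, keywords, garbage, and immediate
# repetitions; used for conservation / order-insensitivity properties
random_log <- function(n_users = 8, n_events = 60, catalog = m4rh_catalog()) {
  texts <- c("m4rh", "mr4h", "66", "66", "61", "77", "88", "99", "dar",
             "hello", "m4rh 66", "xx", "12", "1999")
  users <- sample(sprintf("u%02d", seq_len(n_users)), n_events, replace = TRUE)
  t0 <- as.POSIXct("2015-03-01 08:00:00", tz = TZ)
  when <- t0 + sort(sample.int(90 * 24 * 3600, n_events))
  parse_events(event_log(users, when, sample(texts, n_events, replace = TRUE)),
               catalog)
}

# Independent funnel oracle: base-R scan of every user's full event list,
# with its own stage logic straight off the catalog node table.
brute_force_funnel <- function(cleaned_log, catalog, periods) {
  df <- as.data.frame(cleaned_log)
  nodes <- as.data.frame(catalog$nodes)
  users <- unique(df$user_id)
  res <- data.frame(period = periods$label, new_users = 0L,
                    activated = 0L, active = 0L)
  overall <- c(new = 0L, activated = 0L, active = 0L)
  for (u in users) {
    ev <- df[df$user_id == u, ]
    ev <- ev[order(ev$timestamp), ]
    is_content <- logical(nrow(ev))
    is_submenu <- logical(nrow(ev))
    for (k in seq_len(nrow(ev))) {
      if (ev$parsed_kind[k] == "ward_prefix") {
        is_content[k] <- TRUE
      } else if (ev$parsed_kind[k] == "menu_code") {
        lvl <- nodes$level[nodes$code == ev$parsed_code[k]]
        if (lvl == "content") is_content[k] <- TRUE
        if (lvl == "submenu") is_submenu[k] <- TRUE
      }
    }
    stage <- if (any(is_content)) "active"
             else if (any(is_submenu)) "activated" else "initiated"
    first <- as.Date(min(ev$timestamp), tz = TZ)
    idx <- which(periods$start <= first & first <= periods$end)
    if (length(idx) == 1) {
      res$new_users[idx] <- res$new_users[idx] + 1L
      overall["new"] <- overall["new"] + 1L
      if (stage != "initiated") {
        res$activated[idx] <- res$activated[idx] + 1L
        overall["activated"] <- overall["activated"] + 1L
      }
      if (stage == "active") {
        res$active[idx] <- res$active[idx] + 1L
        overall["active"] <- overall["active"] + 1L
      }
    }
  }
  list(per_period = res, overall = overall)
}

# small but structured simulation used by several test files
small_sim <- function(seed = 42, months = 3, rate = 8, ...) {
  cfg <- simulation_config(
    seed = seed,
    window_start = as.Date("2014-01-01"),
    window_end = as.Date("2014-01-01") + months * 30,
    base_arrival_rate = rate, ...
  )
  simulate_log(cfg)
}
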