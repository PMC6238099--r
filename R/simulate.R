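#' Configuration for the synthetic m4RH-style log generator
#'
#' Defaults reproduce the conditions of the Tanzanian deployment the package
#' was built around: a 36-month window (Sep 2013 - Aug 2016), 381 new users
#' per day, funnel probabilities 0.4610 (activation) and 0.8958 (active use
#' given activation), noise rates equal to the deployment's removal counts
#' over its 4,112,460 raw queries, a bimodal midday/evening access-time
#' mixture, and promotion-month arrival surges. Tests and examples scale the
#' window and arrival rate down; the probabilities are left at the deployment
#' values unless a scenario explicitly varies them.
#'
#' @param seed integer RNG seed; every run with the same config is
#'   bit-identical.
#' @param window_start,window_end study window (`Date`).
#' @param base_arrival_rate expected new users per day (Poisson).
#' @param promo_calendar a [promotion_calendar] of surge months.
#' @param promo_multiplier arrival-rate factor in promotional months.
#' @param p_activate probability an initiated user ever reaches a submenu.
#' @param p_active_given_activated probability an activated user reaches
#'   content.
#' @param p_direct_content probability an active user takes the 2-step path
#'   (content code straight after the welcome menu).
#' @param p_keyword_reentry probability a return session still opens with the
#'   keyword rather than a bare code.
#' @param monthly_return_prob month-to-month retention (geometric): the
#'   probability a user active in one month is active in the next.
#' @param session_query_weights unnormalized weights for 1..k queries per
#'   session.
#' @param extra_sessions_per_month Poisson mean of sessions beyond the first
#'   in each active month.
#' @param time_of_day_weights weights for the midday (12-14 h) peak, the
#'   evening (18-20 h) peak, and the uniform background.
#' @param mean_gap_min mean minutes between consecutive queries in a session
#'   (exponential, truncated to 1-45).
#' @param p_ward_given_clinic probability a clinic-submenu request is
#'   followed by a ward-prefix lookup.
#' @param noise_invalid,noise_duplicate,noise_misspell per-event injection
#'   probabilities for invalid/compound texts, successive duplicate menu
#'   selections, and misspelled keywords.
#' @param submenu_weights named weights (by catalog code) for submenu choice.
#' @param content_weights named weights for content choice within a submenu.
#' @param district_weights named weights for ward-lookup districts.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    window_start = as.Date("2013-09-01"),
    window_end = as.Date("2016-08-31"),
    base_arrival_rate = 381,
    promo_calendar = m4rh_promo_calendar(),
    promo_multiplier = 1.5,
    p_activate = 0.4610,
    p_active_given_activated = 0.8958,
    p_direct_content = 0.30,
    p_keyword_reentry = 0.20,
    monthly_return_prob = 0.37,
    session_query_weights = stats::dpois(0:9, 4),
    extra_sessions_per_month = 0.3,
    time_of_day_weights = c(midday = 0.15, evening = 0.13, background = 0.72),
    mean_gap_min = 17,
    p_ward_given_clinic = 0.333,
    noise_invalid = 35978 / 4112460,
    noise_duplicate = 402780 / 4112460,
    noise_misspell = 5663 / 4112460,
    submenu_weights = c("11" = 16.70, "66" = 52.82, "77" = 11.28,
                        "88" = 16.56, "99" = 5.67),
    content_weights = c("61" = 24.15, "62" = 16.10, "63" = 16.28,
                        "64" = 14.12, "65" = 13.46, "67" = 13.26,
                        "68" = 12.53, "69" = 10.15, "70" = 9.02),
    district_weights = NULL) {
  cfg <- list(
    seed = as.integer(seed), window_start = as.Date(window_start),
    window_end = as.Date(window_end), base_arrival_rate = base_arrival_rate,
    promo_calendar = promo_calendar, promo_multiplier = promo_multiplier,
    p_activate = p_activate,
    p_active_given_activated = p_active_given_activated,
    p_direct_content = p_direct_content,
    p_keyword_reentry = p_keyword_reentry,
    monthly_return_prob = monthly_return_prob,
    session_query_weights = session_query_weights,
    extra_sessions_per_month = extra_sessions_per_month,
    time_of_day_weights = time_of_day_weights,
    mean_gap_min = mean_gap_min,
    p_ward_given_clinic = p_ward_given_clinic,
    noise_invalid = noise_invalid, noise_duplicate = noise_duplicate,
    noise_misspell = noise_misspell,
    submenu_weights = submenu_weights, content_weights = content_weights,
    district_weights = district_weights
  )
  probs <- c(cfg$p_activate, cfg$p_active_given_activated, cfg$p_direct_content,
             cfg$p_keyword_reentry, cfg$monthly_return_prob,
             cfg$p_ward_given_clinic,
             cfg$noise_invalid, cfg$noise_duplicate, cfg$noise_misspell)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$session_query_weights < 0) || sum(cfg$session_query_weights) <= 0) {
    stop("session_query_weights must be nonnegative and normalizable", call. = FALSE)
  }
  if (cfg$window_end < cfg$window_start) stop("empty window", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Bundled synthetic ward-prefix to district map
#'
#' One invented 3-4 letter prefix per district of the deployment's ward
#' table. Synthetic: real ward names (and hence real prefixes) are not
#' public.
#'
#' @return tibble with columns `prefix`, `district`.
#' @export
synthetic_ward_districts <- function() {
  readr::read_csv(system.file("extdata", "synthetic_ward_districts.csv",
                              package = "m4rhfunnel", mustWork = TRUE),
                  col_types = "cc", progress = FALSE)
}

# default per-district weights: the deployment's ward-request shares
default_district_weights <- function(district_map) {
  shares <- c("Dar es Salaam" = 50.91, "Dodoma" = 9.65, "Mwanza" = 8.52,
              "Arusha" = 7.60, "Mbeya" = 3.90, "Kigoma" = 3.37,
              "Tanga" = 2.49, "Njombe" = 2.44, "Iringa" = 2.25,
              "Geita" = 2.20, "Morogoro" = 2.04, "Pwani" = 1.80,
              "Simiyu" = 1.09, "Ruvuma" = 0.88, "Singida" = 0.67,
              "Mjini Magharibi" = 0.17, "Mara" = 0.01)
  w <- shares[district_map$district]
  w[is.na(w)] <- 1
  setNames(as.numeric(w), district_map$district)
}

# one draw from the midday/evening/background time-of-day mixture, in hours
draw_start_hour <- function(n, weights) {
  comp <- sample(c("midday", "evening", "background"), n, replace = TRUE,
                 prob = weights[c("midday", "evening", "background")])
  h <- runif(n, 0, 24)
  h[comp == "midday"] <- runif(sum(comp == "midday"), 12, 14)
  h[comp == "evening"] <- runif(sum(comp == "evening"), 18, 20)
  h
}

sample_one <- function(x, weights = NULL) {
  if (length(x) == 1) return(x)
  sample(x, 1, prob = weights)
}

#' Simulate an m4RH-style SMS query log with known ground truth
#'
#' Arrivals follow a day-level Poisson process whose rate is scaled by
#' `promo_multiplier` in promotional months. Each new user draws a latent
#' funnel stage (initiated / activated / active) from the funnel
#' probabilities and a geometric number of active months; each active month
#' holds one or more sessions, each on its own calendar day. A session is a
#' burst of queries: a keyword (always for the first-ever session; with
#' probability `p_keyword_reentry` for re-entries, since experienced users
#' texted codes directly), then menu codes drawn from the catalog nodes
#' active on the session date, never repeating the immediately preceding
#' code; clinic-submenu requests are followed by a ward-prefix lookup with
#' probability `p_ward_given_clinic`. Sessions never cross midnight, so the
#' noise-free base log contains no successive duplicate menu selections by
#' construction. Noise (invalid/compound texts, successive duplicates,
#' misspelled keywords) is injected afterwards, and the realized injection
#' counts are recorded in the ground truth so the cleaning ledger can be
#' validated exactly.
#'
#' @param config a [simulation_config].
#' @param catalog the [menu_catalog] to draw codes from.
#' @param district_map ward-prefix map for clinic lookups (default the
#'   bundled synthetic one).
#' @return list with `log` (an unparsed `event_log`, in timestamp order) and
#'   `truth` (a `ground_truth`: `users` tibble with `user_id`, `arrival_day`,
#'   `stage`, `n_months`, `is_return`; realized injection counts and
#'   eligible-event counts; the config).
#' @export
simulate_log <- function(config = simulation_config(),
                         catalog = m4rh_catalog(),
                         district_map = synthetic_ward_districts()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  dw <- config$district_weights %||% default_district_weights(district_map)
  districts <- unique(district_map$district)
  dw <- setNames(dw[districts], districts)
  dw[is.na(dw)] <- 1

  days <- seq(config$window_start, config$window_end, by = "day")
  mk <- format(days, "%Y-%m")
  lambda <- config$base_arrival_rate *
    ifelse(mk %in% unclass(config$promo_calendar), config$promo_multiplier, 1)
  n_new <- rpois(length(days), lambda)
  n_users <- sum(n_new)

  if (n_users == 0) {
    log <- event_log()
    truth <- structure(
      list(users = tibble::tibble(user_id = character(),
                                  arrival_day = as.Date(character()),
                                  stage = character(), n_months = integer(),
                                  is_return = logical()),
           injected = c(invalid = 0L, duplicate = 0L, misspell = 0L),
           eligible = c(invalid = 0L, duplicate = 0L, misspell = 0L),
           config = config),
      class = "ground_truth")
    return(list(log = log, truth = truth))
  }

  # seed-prefixed ids: logs from different seeds share no users
  users <- tibble::tibble(
    user_id = sprintf("s%d-u%07d", config$seed, seq_len(n_users)),
    arrival_day = rep(days, n_new)
  )
  activated <- runif(n_users) < config$p_activate
  active <- activated & runif(n_users) < config$p_active_given_activated
  users$stage <- ifelse(active, "active", ifelse(activated, "activated", "initiated"))
  users$direct <- active & runif(n_users) < config$p_direct_content
  extra_months <- rgeom(n_users, max(1 - config$monthly_return_prob, 1e-12))

  window_last_month <- format(config$window_end, "%Y-%m")
  first_month <- lubridate::floor_date(users$arrival_day, "month")
  clinic_code <- catalog_codes(catalog, "ward_lookup")
  clinic_parent <- catalog$nodes$parent[catalog$nodes$level == "ward_lookup"]
  misspellings <- catalog$misspellings
  invalid_pool <- c("hello", "nipe taarifa", "asante sana", "12345", "habari",
                    paste(catalog$keyword, "66"))

  n_q_values <- seq_along(config$session_query_weights)

  # numeric accumulation: POSIXct arithmetic / per-session tibbles are too
  # slow at deployment scale
  all_days <- days
  day_start_sec <- as.numeric(as.POSIXct(paste(all_days, "00:00:00"),
                                         tz = M4RH_TZ))
  uid_acc <- vector("list", 4096); ts_acc <- vector("list", 4096)
  tx_acc <- vector("list", 4096); acc_k <- 0L
  push <- function(u, ts, tx) {
    acc_k <<- acc_k + 1L
    if (acc_k > length(uid_acc)) {
      length(uid_acc) <<- 2L * acc_k
      length(ts_acc) <<- 2L * acc_k
      length(tx_acc) <<- 2L * acc_k
    }
    uid_acc[[acc_k]] <<- rep(u, length(tx))
    ts_acc[[acc_k]] <<- ts
    tx_acc[[acc_k]] <<- tx
  }
  n_months_realized <- integer(n_users)

  # date-gated code pools change only at active_from boundaries; precompute
  gates <- sort(unique(catalog$nodes$active_from[!is.na(catalog$nodes$active_from)]))
  pool_key <- function(day) sum(gates <= day) + 1L
  pools <- lapply(seq_len(length(gates) + 1L), function(k) {
    ref_day <- if (k == 1) min(all_days) - 1 else gates[k - 1]
    submenus <- catalog_codes(catalog, "submenu", ref_day)
    contents <- catalog_codes(catalog, "content", ref_day)
    sw <- setNames(config$submenu_weights[submenus], submenus)
    sw[is.na(sw)] <- 1
    cw <- setNames(config$content_weights[contents], contents)
    cw[is.na(cw)] <- 1
    list(submenus = submenus, contents = contents, sw = sw, cw = cw)
  })

  for (i in seq_len(n_users)) {
    u <- users$user_id[i]
    stage <- users$stage[i]
    months <- seq(first_month[i], by = "month",
                  length.out = extra_months[i] + 1L)
    months <- months[format(months, "%Y-%m") <= window_last_month]
    n_months_realized[i] <- length(months)

    sess_days <- list()
    for (m in seq_along(months)) {
      m_start <- months[m]
      m_end <- min(lubridate::ceiling_date(m_start, "month") - 1, config$window_end)
      pool <- seq(if (m == 1) users$arrival_day[i] else m_start, m_end, by = "day")
      n_sess <- min(1L + rpois(1, config$extra_sessions_per_month), length(pool))
      d <- if (m == 1) {
        c(users$arrival_day[i],
          if (n_sess > 1) sample_one_or_more(setdiff(pool, users$arrival_day[i]),
                                             n_sess - 1L))
      } else {
        sample_one_or_more(pool, n_sess)
      }
      sess_days[[m]] <- sort(unique(d))
    }
    sess_days <- as.Date(unlist(sess_days), origin = "1970-01-01")

    first_session <- TRUE
    for (d in seq_along(sess_days)) {
      day <- sess_days[d]
      n_q <- sample(n_q_values, 1, prob = config$session_query_weights)
      # enforce minimum depth on the first-ever session so the latent stage
      # is always expressed in the log
      if (first_session) {
        if (stage == "initiated") n_q <- 1L
        if (stage == "activated") n_q <- max(n_q, 2L)
        if (stage == "active") n_q <- max(n_q, if (users$direct[i]) 2L else 3L)
      }
      open_kw <- first_session || runif(1) < config$p_keyword_reentry
      texts <- character(0)
      if (open_kw) texts <- catalog$keyword
      if (stage == "initiated") {
        texts <- catalog$keyword  # keyword is all they ever send
      } else {
        pl <- pools[[pool_key(day)]]
        submenus <- pl$submenus; contents <- pl$contents
        sw <- pl$sw; cw <- pl$cw
        need <- n_q - length(texts)
        last_code <- NA_character_
        forced_content_done <- !(first_session && stage == "active")
        while (need > 0) {
          if (stage == "activated") {
            cand <- setdiff(submenus, last_code)
            code <- sample_one(cand, sw[cand])
          } else if (!forced_content_done && users$direct[i]) {
            code <- sample_one(setdiff(contents, last_code),
                               cw[setdiff(contents, last_code)])
            forced_content_done <- TRUE
          } else if (!forced_content_done && need == 1) {
            code <- sample_one(setdiff(contents, last_code),
                               cw[setdiff(contents, last_code)])
            forced_content_done <- TRUE
          } else {
            pool2 <- c(submenus, contents)
            w2 <- c(sw, cw)
            cand <- setdiff(pool2, last_code)
            code <- sample_one(cand, w2[cand])
            if (code %in% contents) forced_content_done <- TRUE
          }
          texts <- c(texts, code)
          last_code <- code
          need <- need - 1L
          # clinic submenu can trigger a ward lookup (a content-level act,
          # so only latent-active users follow through)
          if (stage == "active" &&
              length(clinic_parent) == 1 && code == clinic_parent &&
              runif(1) < config$p_ward_given_clinic) {
            distr <- sample_one(districts, dw[districts])
            pref <- tolower(sample_one(district_map$prefix[district_map$district == distr]))
            texts <- c(texts, pref)
            last_code <- pref
            forced_content_done <- TRUE
          }
        }
      }
      # timestamps: whole seconds, >= 60 s apart, never crossing midnight
      gaps <- pmin(pmax(round(rexp(max(length(texts) - 1, 0),
                                   1 / config$mean_gap_min)), 1), 45)
      total_min <- sum(gaps)
      start_h <- draw_start_hour(1, config$time_of_day_weights)
      start_min <- min(start_h * 60, 24 * 60 - total_min - 5)
      start_min <- max(start_min, 2)  # leave room for a misspelling insert
      ts <- day_start_sec[match(day, all_days)] +
        round(start_min * 60) + c(0, cumsum(gaps * 60))
      push(u, ts, texts)
      first_session <- FALSE
    }
  }

  base <- tibble::tibble(
    user_id = unlist(uid_acc[seq_len(acc_k)]),
    timestamp = lubridate::as_datetime(unlist(ts_acc[seq_len(acc_k)]),
                                       tz = M4RH_TZ),
    text = unlist(tx_acc[seq_len(acc_k)])
  )
  base <- base[order(base$user_id, base$timestamp), ]

  # ---- noise injection (post hoc; ground truth records realized counts) ----
  parsed <- parse_query_text(base$text, catalog, as.Date(base$timestamp, tz = M4RH_TZ))
  has_code <- parsed$parsed_kind %in% c("menu_code", "ward_prefix")
  is_kw <- parsed$parsed_kind == "keyword"
  secs_to_midnight <- 24 * 3600 -
    as.numeric(difftime(base$timestamp,
                        lubridate::floor_date(base$timestamp, "day"),
                        units = "secs"))

  dup_ok <- has_code & secs_to_midnight > 30
  dup_sel <- dup_ok & runif(nrow(base)) < config$noise_duplicate
  dup_rows <- base[dup_sel, ]
  if (nrow(dup_rows) > 0) {
    dup_rows$timestamp <- dup_rows$timestamp + sample(5:25, nrow(dup_rows), TRUE)
  }

  inv_sel <- runif(nrow(base)) < config$noise_invalid
  inv_rows <- base[inv_sel, ]
  if (nrow(inv_rows) > 0) {
    inv_rows$timestamp <- inv_rows$timestamp + sample(30:55, nrow(inv_rows), TRUE)
    inv_rows$text <- sample(invalid_pool, nrow(inv_rows), TRUE)
  }

  mis_sel <- is_kw & runif(nrow(base)) < config$noise_misspell
  mis_rows <- base[mis_sel, ]
  if (nrow(mis_rows) > 0) {
    mis_rows$timestamp <- mis_rows$timestamp - sample(30:90, nrow(mis_rows), TRUE)
    mis_rows$text <- sample(misspellings, nrow(mis_rows), TRUE)
  }

  all_rows <- dplyr::bind_rows(base, dup_rows, inv_rows, mis_rows)
  all_rows <- all_rows[order(all_rows$timestamp, all_rows$user_id), ]

  users$n_months <- n_months_realized
  users$is_return <- n_months_realized >= 2
  users$direct <- NULL

  log <- new_event_log(all_rows,
                       provenance = list(source = "simulate_log",
                                         n_input_rows = nrow(all_rows),
                                         n_rejected = 0L))
  truth <- structure(
    list(users = users,
         injected = c(invalid = nrow(inv_rows), duplicate = nrow(dup_rows),
                      misspell = nrow(mis_rows)),
         eligible = c(invalid = nrow(base), duplicate = sum(dup_ok),
                      misspell = sum(is_kw)),
         config = config),
    class = "ground_truth")
  list(log = log, truth = truth)
}

# sample n elements without replacement (base::sample misbehaves on length-1 x)
sample_one_or_more <- function(x, n) {
  n <- min(n, length(x))
  if (n <= 0) return(x[0])
  x[sample.int(length(x), n)]
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$users), " users (",
      sum(x$users$stage == "active"), " active, ",
      sum(x$users$stage == "activated"), " activated-only); injected noise: ",
      paste(names(x$injected), x$injected, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Recover generative parameters from a simulated log
#'
#' Runs the full pipeline — parse, clean, journey reconstruction, funnel
#' classification — on a (typically simulated) raw log and returns the point
#' estimates that correspond to the generator's funnel probabilities, for
#' parameter-recovery validation.
#'
#' @param log a raw `event_log`.
#' @param catalog the [menu_catalog].
#' @return list with `activation` (share of users reaching a submenu or
#'   deeper), `active_use` (share of activated users reaching content),
#'   `monthly_return` (share of users active in >= 2 months), `n_users`, and
#'   the `cleaning_report`.
#' @export
recover_parameters <- function(log, catalog = m4rh_catalog()) {
  cleaned <- clean(parse_events(log, catalog))
  j <- build_journeys(cleaned$log, catalog)
  n <- nrow(j)
  n_act <- sum(j$max_stage %in% c("activated", "active"))
  n_acv <- sum(j$max_stage == "active")
  list(
    activation = if (n > 0) n_act / n else NA_real_,
    active_use = if (n_act > 0) n_acv / n_act else NA_real_,
    monthly_return = if (n > 0) length(classify_return_users(j)) / n else NA_real_,
    n_users = n,
    cleaning_report = cleaned$report
  )
}
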