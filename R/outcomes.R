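# Outcome construction: patient presentation rate (PPR) and transfer to
# hospital rate (TTHR), both expressed per 10,000 attendees with the event
# edition as the unit of analysis.

official_days_of <- function(edition) {
  first <- as.Date(edition$first_day)
  n <- as.integer(edition$n_days)
  if (is.na(first) || is.na(n) || n < 1) {
    mur_stop("Edition has no valid official days (first_day/n_days).",
             class = "murtree_error_domain")
  }
  seq(first, by = "day", length.out = n)
}

resolve_attendance <- function(edition) {
  att <- edition$attendance
  if (is.na(att)) {
    mur_stop(
      sprintf("Attendance unresolved for event '%s': outcome undefined.",
              edition$event_id),
      class = "murtree_error_outcome_undefined"
    )
  }
  if (att <= 0) {
    mur_stop("Attendance must be positive.", class = "murtree_error_domain")
  }
  att
}

#' Patient presentation rate of one event edition
#'
#' Counts every patient encounter dated on an official event day — regardless
#' of missing age or dismissal fields — and scales to attendees. Encounters
#' registered the day before or after an official event day (typical for
#' multi-day festivals with camping) are excluded.
#'
#' @param encounters Data frame of patient encounter forms with at least
#'   `event_id` and `day` (Date). Only rows matching `edition$event_id` are
#'   used; pass a pre-filtered table or the full registry.
#' @param edition One-row data frame for the event edition (needs `event_id`,
#'   `attendance`, `first_day`, `n_days`).
#' @return PPR per 10,000 attendees (full precision; round only for display).
#' @seealso [compute_tthr()], [aggregate_events()]
#' @export
compute_ppr <- function(encounters, edition) {
  att <- resolve_attendance(edition)
  days <- official_days_of(edition)
  enc <- encounters[encounters$event_id == edition$event_id, , drop = FALSE]
  n_pat <- sum(as.Date(enc$day) %in% days)
  10000 * n_pat / att
}

#' Transfer to hospital rate of one event edition
#'
#' Counts encounters on official event days whose dismissal destination is a
#' hospital transfer by ambulance. Transport by own means is not a transfer,
#' and a missing dismissal field counts as a non-transfer (the conservative
#' reading: the dominant "back to the event" destination is the one most
#' easily left blank, so TTHR may be slightly overestimated in real
#' registries, never underestimated by this rule).
#'
#' @inheritParams compute_ppr
#' @return TTHR per 10,000 attendees.
#' @export
compute_tthr <- function(encounters, edition) {
  att <- resolve_attendance(edition)
  days <- official_days_of(edition)
  enc <- encounters[encounters$event_id == edition$event_id, , drop = FALSE]
  in_window <- as.Date(enc$day) %in% days
  is_transfer <- !is.na(enc$dismissal) & enc$dismissal == "hospital_by_ambulance"
  10000 * sum(in_window & is_transfer) / att
}

#' Attendance class
#'
#' Bins cumulative attendance into the six classes used as a tree predictor.
#' Bins are half-open on the right: \[0, 10k), \[10k, 20k), \[20k, 30k),
#' \[30k, 100k), \[100k, 1M), \[1M, Inf).
#'
#' @param attendance Positive attendee count(s), cumulative over days.
#' @return Ordered factor with levels `lt10k < a10_20k < a20_30k < a30_100k <
#'   a100k_1M < gt1M`.
#' @export
classify_attendance <- function(attendance) {
  if (any(is.na(attendance)) || any(attendance <= 0)) {
    mur_stop("Attendance must be positive and non-missing.",
             class = "murtree_error_domain")
  }
  cut(attendance,
      breaks = c(0, 1e4, 2e4, 3e4, 1e5, 1e6, Inf),
      labels = mur_levels$attendance_class,
      right = FALSE, ordered_result = TRUE)
}

#' Age class of an event's patient population
#'
#' Classifies the audience from the median, first quartile and interquartile
#' range of non-missing patient ages. A broad age spread marks the
#' mixed/family class and takes precedence: Q1 < 21 y with IQR > 20 y, or
#' Q1 < 18 y with IQR > 15 y. Otherwise the median decides: children
#' (< 16 y), young adults (16–30 y), middle adults (> 30 y).
#'
#' @param age_median,age_q1,age_iqr Age statistics in years, computed on
#'   non-missing ages.
#' @return Factor with levels `children`, `young_adults`, `middle_adults`,
#'   `mixed_family`.
#' @export
classify_age <- function(age_median, age_q1, age_iqr) {
  if (any(is.na(c(age_median, age_q1, age_iqr)))) {
    mur_stop("Age statistics unavailable (all ages missing?): cannot classify.",
             class = "murtree_error_classification")
  }
  mixed <- (age_q1 < 21 & age_iqr > 20) | (age_q1 < 18 & age_iqr > 15)
  out <- ifelse(mixed, "mixed_family",
         ifelse(age_median < 16, "children",
         ifelse(age_median <= 30, "young_adults", "middle_adults")))
  factor(out, levels = mur_levels$age_class)
}

#' Number-of-days class
#'
#' @param n_days Number of official event days (or a list/vector of dates,
#'   in which case its length is used).
#' @return Ordered factor `d1 < d2 < d3plus`.
#' @export
classify_days <- function(n_days) {
  if (!is.numeric(n_days)) n_days <- lengths(n_days)
  if (any(is.na(n_days)) || any(n_days < 1)) {
    mur_stop("Need at least one official day.", class = "murtree_error_domain")
  }
  out <- ifelse(n_days == 1, "d1", ifelse(n_days == 2, "d2", "d3plus"))
  factor(out, levels = mur_levels$days_class, ordered = TRUE)
}

#' Resolve missing attendance within a mass-gathering series
#'
#' Applies the two documented registry rules, and only those: (1) a single
#' missing year flanked by two observed editions is interpolated as the
#' arithmetic mean of the previous and following edition; (2) when the first
#' edition of a sold-out series reported its attendance, later sold-out
#' editions with missing attendance copy the first edition's figure. Any
#' other missing value is an error — no further imputation is attempted.
#'
#' @param series Data frame of the editions of one mass gathering, with
#'   columns `event_id`, `year`, `attendance`, `sold_out`; rows are sorted by
#'   `year` internally.
#' @return The series as a tibble with `attendance` resolved and a provenance
#'   column `attendance_source` (`observed`, `interpolated` or
#'   `sold_out_copy`).
#' @export
impute_attendance <- function(series) {
  series <- as_tibble(series) |> arrange(.data$year)
  att <- series$attendance
  src <- rep("observed", length(att))
  miss <- which(is.na(att))
  if (length(miss) == 0) {
    series$attendance_source <- src
    return(series)
  }
  first_sold_out <- isTRUE(series$sold_out[1]) && !is.na(att[1])
  for (i in miss) {
    interior <- i > 1 && i < length(att) &&
      !is.na(att[i - 1]) && !is.na(att[i + 1])
    if (interior) {
      att[i] <- (att[i - 1] + att[i + 1]) / 2
      src[i] <- "interpolated"
    } else if (first_sold_out && isTRUE(series$sold_out[i]) && i > 1) {
      att[i] <- series$attendance[1]
      src[i] <- "sold_out_copy"
    } else {
      mur_stop(
        sprintf(
          "Attendance for '%s' (year %s) matches neither imputation rule.",
          series$event_id[i], series$year[i]),
        class = "murtree_error_unresolvable_missing"
      )
    }
  }
  series$attendance <- att
  series$attendance_source <- src
  series
}

#' Events per candidate predictor variable
#'
#' The EPV overfitting heuristic: number of outcome events divided by the
#' number of candidate predictors, reported to one decimal. Values above 10
#' are conventionally considered safe for model development.
#'
#' @param n_events Number of events (editions) in the development set.
#' @param n_candidates Number of candidate predictor variables (>= 1).
#' @return One-row tibble with `n_events`, `n_candidates`, `epv`.
#' @export
compute_epv <- function(n_events, n_candidates) {
  if (n_candidates < 1) {
    mur_stop("Need at least one candidate predictor.",
             class = "murtree_error_domain")
  }
  tibble(n_events = n_events, n_candidates = n_candidates,
         epv = round_report(n_events / n_candidates, 1))
}

#' Aggregate a registry into the event-level analysis table
#'
#' Pools encounters by event edition and builds the regression unit of
#' analysis: outcomes (PPR, TTHR per 10,000), categorized predictors
#' (attendance, age, days classes) and age summary statistics. Attendance is
#' resolved first via [impute_attendance()] within each series. Age quantiles
#' use the inclusive linear-interpolation convention (`stats::quantile`
#' type 7) on non-missing ages only.
#'
#' @param events Event-edition table (see [read_events()] for the schema).
#' @param encounters Patient-encounter table (see [read_encounters()]).
#' @return Tibble with one row per event edition: the raw event fields,
#'   `attendance_source`, `n_patients`, `n_transfers`, `ppr`, `tthr`,
#'   `attendance_class`, `age_class`, `days_class`, `age_median`, `age_q1`,
#'   `age_iqr`.
#' @export
aggregate_events <- function(events, encounters) {
  events <- as_tibble(events) |>
    group_by(.data$series_name) |>
    group_modify(~ impute_attendance(.x)) |>
    ungroup() |>
    relocate("series_name", .after = "event_id")

  per_event <- function(ed) {
    enc <- encounters[encounters$event_id == ed$event_id, , drop = FALSE]
    days <- official_days_of(ed)
    enc <- enc[as.Date(enc$day) %in% days, , drop = FALSE]
    ages <- enc$age[!is.na(enc$age)]
    if (length(ages) > 0) {
      qs <- quantile(ages, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      stats <- tibble(age_median = qs[2], age_q1 = qs[1], age_iqr = qs[3] - qs[1])
    } else {
      stats <- tibble(age_median = NA_real_, age_q1 = NA_real_,
                      age_iqr = NA_real_)
    }
    tibble(
      n_patients = nrow(enc),
      n_transfers = sum(!is.na(enc$dismissal) &
                          enc$dismissal == "hospital_by_ambulance"),
      ppr = compute_ppr(enc, ed),
      tthr = compute_tthr(enc, ed)
    ) |> bind_cols(stats)
  }

  out <- bind_cols(events,
                   purrr::map_dfr(seq_len(nrow(events)),
                                  ~ per_event(events[.x, ])))
  out |>
    mutate(
      attendance_class = classify_attendance(.data$attendance),
      age_class = classify_age(.data$age_median, .data$age_q1, .data$age_iqr),
      days_class = classify_days(.data$n_days),
      category = factor(.data$category, levels = mur_levels$category),
      timing = factor(.data$timing, levels = mur_levels$timing),
      alcohol = factor(.data$alcohol, levels = mur_levels$alcohol)
    )
}
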