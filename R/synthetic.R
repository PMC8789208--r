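# Synthetic registry generator. Emulates the structure of a national
# mass-gathering first-aid registry — recurring events with editions,
# per-patient encounter forms, daily temperatures — with a known
# piecewise-constant ground truth, so the whole pipeline (outcome
# construction, tree fitting, temperature transfer, cascaded TTHR,
# validation) can be exercised and parameter recovery measured without the
# proprietary data.

default_true_effects <- function() {
  # expected PPR per 10,000 by predictor profile: a piecewise-constant
  # function over category, with a number-of-days split inside outdoor
  # music (long festivals run much hotter than one/two-day editions).
  # Values span the 12-273 range typical of fitted leaves, separated so
  # that every generating split clears the 1%-of-root-SSE complexity gate
  # at the default group sizes. The two small indoor categories share a
  # rate (indoor dance crowds present like indoor EDM crowds), which keeps
  # each distinct-rate group large enough to be recoverable.
  tibble(
    profile_id = c("city", "dance", "sports", "iedm", "oedm",
                   "om_short", "om_long"),
    category = c("city_festival", "indoor_dance", "sports_event",
                 "indoor_edm", "outdoor_edm", "outdoor_music",
                 "outdoor_music"),
    days_rule = c("any", "any", "any", "any", "any", "short", "long"),
    true_ppr = c(12, 120, 64, 120, 176, 225, 273)
  )
}

default_true_tthr_effects <- function() {
  # expected TTHR per 10,000 keyed by the PPR ground-truth profile: a
  # function of the PPR leaf, spanning 0.3-5.9 (indoor EDM highest).
  # Neighbouring values are deliberately close: at realistic transfer
  # counts the complexity gate lumps them, as real TTHR trees do.
  c(city = 0.3, dance = 1.0, sports = 1.7, iedm = 5.9, oedm = 4.0,
    om_short = 2.2, om_long = 2.2)
}

#' Synthetic-registry generator configuration
#'
#' Defaults describe the study conditions the generator emulates: 25 series
#' of 8 editions (200 events), a category mix shaped on the development
#' dataset of a Belgian mass-gathering registry (44% outdoor music, 19%
#' city festivals, ...), piecewise-constant expected PPR over predictor
#' profiles spanning 12–273 per 10,000, expected TTHR per PPR profile
#' spanning 0.3–5.9, a linear temperature effect on outdoor summer events
#' (slope 7.6 PPR per degree on the daily maximum, pivot 25.6 C, anchored
#' at the long-festival rate of 273 so the registry's temperature law and
#' the day-level reference series share one anchor), 23% missing age and
#' 10% missing dismissal destination.
#'
#' @param n_series Number of recurring mass gatherings.
#' @param editions_per_series Editions per series.
#' @param category_mix Named probabilities over the six categories.
#' @param true_effects Profile rule table (see source) with `true_ppr`.
#' @param true_tthr_effects Named vector: expected TTHR per profile.
#' @param temp_which Temperature variable driving the true effect.
#' @param temp_slope,temp_pivot,reference_ppr Linear transfer ground truth.
#' @param noise_sd Event-level additive PPR noise (per 10,000). `0` is the
#'   exact oracle mode: event noise and count sampling are both switched
#'   off and patient counts are deterministic rounded expectations.
#' @param ref_noise_sd Day-level PPR noise of the reference event.
#' @param missing_age_rate,missing_dismissal_rate PEF missingness rates.
#' @param temp_constant When non-`NULL`, every day's temperature (both
#'   variants) is fixed at this value instead of the seasonal draw.
#' @param first_year First edition year.
#' @param seed Generator seed; everything is reproducible from it.
#' @return A `mur_synth_config` list.
#' @export
synth_config <- function(n_series = 25L, editions_per_series = 8L,
                         category_mix = c(city_festival = 0.19,
                                          indoor_edm = 0.10,
                                          indoor_dance = 0.06,
                                          outdoor_edm = 0.11,
                                          outdoor_music = 0.44,
                                          sports_event = 0.10),
                         true_effects = default_true_effects(),
                         true_tthr_effects = default_true_tthr_effects(),
                         temp_which = c("t_max", "t_av"),
                         temp_slope = 7.6, temp_pivot = 25.6,
                         reference_ppr = 273,
                         noise_sd = 5, ref_noise_sd = 20,
                         missing_age_rate = 0.23,
                         missing_dismissal_rate = 0.10,
                         temp_constant = NULL,
                         first_year = 2009L, seed = 1L) {
  if (abs(sum(category_mix) - 1) > 1e-8 || any(category_mix < 0)) {
    mur_stop("category_mix must be non-negative probabilities summing to 1.",
             class = "murtree_error_config")
  }
  if (missing_age_rate < 0 || missing_age_rate > 1 ||
      missing_dismissal_rate < 0 || missing_dismissal_rate > 1 ||
      noise_sd < 0) {
    mur_stop("Rates must be in [0, 1] and noise_sd >= 0.",
             class = "murtree_error_config")
  }
  structure(list(
    n_series = as.integer(n_series),
    editions_per_series = as.integer(editions_per_series),
    category_mix = category_mix[mur_levels$category],
    true_effects = true_effects,
    true_tthr_effects = true_tthr_effects,
    temp_which = match.arg(temp_which),
    temp_slope = temp_slope, temp_pivot = temp_pivot,
    reference_ppr = reference_ppr,
    noise_sd = noise_sd, ref_noise_sd = ref_noise_sd,
    missing_age_rate = missing_age_rate,
    missing_dismissal_rate = missing_dismissal_rate,
    temp_constant = temp_constant,
    first_year = as.integer(first_year),
    seed = as.integer(seed)
  ), class = "mur_synth_config")
}

lookup_profile <- function(effects, category, n_days) {
  rule <- effects[effects$category == category, ]
  if (nrow(rule) == 1) return(rule$profile_id)
  if (n_days >= 3) rule$profile_id[rule$days_rule == "long"]
  else rule$profile_id[rule$days_rule == "short"]
}

draw_ages <- function(n, profile) {
  switch(profile,
    children = pmin(pmax(rnorm(n, 12, 2), 3), 15),
    young_adults = pmin(pmax(rnorm(n, 24, 3.5), 16), 45),
    middle_adults = pmin(pmax(rnorm(n, 38, 6), 18), 80),
    mixed_family = runif(n, 5, 60)
  )
}

seasonal_temps <- function(days, config) {
  if (!is.null(config$temp_constant)) {
    return(tibble(day = days, t_av_c = config$temp_constant,
                  t_max_c = config$temp_constant))
  }
  doy <- as.integer(format(days, "%j"))
  t_max <- 16 + 10 * cos(2 * pi * (doy - 197) / 365) + rnorm(length(days), 0, 3)
  t_av <- t_max - 5.2 + rnorm(length(days), 0, 1)
  tibble(day = days, t_av_c = round(t_av, 1), t_max_c = round(t_max, 1))
}

#' Generate a synthetic mass-gathering registry
#'
#' Draws a full registry — event editions, patient encounter forms and
#' daily temperatures — from the configured ground truth. For each event,
#' the expected PPR is its profile's true value plus, for outdoor
#' June–September events, the linear temperature term
#' `true/reference * slope * (T - pivot)`; the realized patient count is
#' Poisson with that expectation (after additive event-level noise), or the
#' deterministic rounded expectation when `noise_sd = 0`. Transfers are
#' drawn analogously from the TTHR ground truth. Encounter ages follow the
#' event's age-profile mixture with the configured missingness.
#'
#' @param config A [synth_config()].
#' @return A `mur_registry` list: `events`, `encounters`, `temperatures`
#'   (tibbles matching the reader schemas) and `ground_truth` (per-event
#'   expected rates and profile, with the generating structure as
#'   attributes).
#' @export
generate_registry <- function(config = synth_config()) {
  with_preserved_seed(config$seed, generate_registry_impl(config))
}

generate_registry_impl <- function(config) {
  n_series <- config$n_series
  # deterministic largest-remainder apportionment of series to categories,
  # so every category mix share is honoured exactly at any n_series
  quota <- config$category_mix * n_series
  counts <- floor(quota)
  rem <- n_series - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  cats <- rep(mur_levels$category, times = counts)
  # deterministic spread of per-series attributes
  series <- tibble(
    series_name = sprintf("series_%02d", seq_len(n_series)),
    category = cats,
    indoor = cats %in% c("indoor_edm", "indoor_dance"),
    # development eligibility: at least 10,000 attendees per edition
    base_attendance = pmin(pmax(round(exp(rnorm(n_series, log(5e4), 0.9)),
                                      -3), 1e4), 1.5e6),
    bounded = runif(n_series) < 0.8,
    age_profile = dplyr::case_when(
      cats == "city_festival" ~ "mixed_family",
      cats == "sports_event" ~ "middle_adults",
      TRUE ~ sample(c("young_adults", "mixed_family", "children",
                      "middle_adults"), n_series, replace = TRUE,
                    prob = c(0.8, 0.1, 0.05, 0.05))
    ),
    # outdoor music alternates short and long editions across series so the
    # days split inside that category is learnable
    n_days = dplyr::case_when(
      cats == "outdoor_music" ~ rep(c(1L, 2L, 3L, 4L),
                                    length.out = n_series),
      cats %in% c("indoor_edm", "indoor_dance", "outdoor_edm") ~
        sample(1:2, n_series, replace = TRUE),
      TRUE ~ sample(c(1L, 1L, 2L, 3L), n_series, replace = TRUE)
    ),
    timing = dplyr::case_when(
      cats %in% c("indoor_edm", "indoor_dance", "outdoor_edm") ~ "night",
      cats == "sports_event" ~ "day",
      TRUE ~ "day_and_night"
    ),
    alcohol = dplyr::case_when(
      age_profile == "children" ~ "none",
      cats == "sports_event" ~ "limited",
      TRUE ~ "unlimited"
    ),
    hospital_distance_km = round(runif(n_series, 1, 25), 1),
    # summer slot for outdoor events, winter for indoor
    start_month = ifelse(cats %in% c("indoor_edm", "indoor_dance"),
                         sample(c(2L, 3L, 11L), n_series, replace = TRUE),
                         sample(6:8, n_series, replace = TRUE)),
    start_dom = sample(1:24, n_series, replace = TRUE)
  )
  series$camping <- series$category == "outdoor_music" & series$n_days >= 3
  series$hospital_time_min <- round(2 * series$hospital_distance_km +
                                      runif(n_series, 2, 8), 0)

  events <- tidyr::expand_grid(series, edition = seq_len(config$editions_per_series)) |>
    mutate(
      year = config$first_year + .data$edition - 1L,
      event_id = sprintf("%s_%d", .data$series_name, .data$year),
      attendance = pmax(round(.data$base_attendance *
                                runif(n(), 0.9, 1.1), -2), 1e4),
      first_day = as.Date(sprintf("%d-%02d-%02d", .data$year,
                                  .data$start_month, .data$start_dom)),
      sold_out = FALSE
    )

  all_days <- sort(unique(as.Date(unlist(purrr::map2(
    events$first_day, events$n_days,
    ~ seq(.x, by = "day", length.out = .y))), origin = "1970-01-01")))
  temperatures <- seasonal_temps(all_days, config)
  tcol <- paste0(config$temp_which, "_c")

  truth <- purrr::map(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    profile <- lookup_profile(config$true_effects, ev$category, ev$n_days)
    true_ppr <- config$true_effects$true_ppr[
      config$true_effects$profile_id == profile]
    days <- seq(ev$first_day, by = "day", length.out = ev$n_days)
    adjustable <- !ev$indoor &&
      all(as.integer(format(days, "%m")) %in% 6:9)
    t_event <- mean(temperatures[[tcol]][temperatures$day %in% days])
    expected <- true_ppr
    if (adjustable) {
      expected <- expected + true_ppr / config$reference_ppr *
        config$temp_slope * (t_event - config$temp_pivot)
    }
    expected <- max(expected, 0.5)
    tibble(event_id = ev$event_id, profile_id = profile,
           true_ppr = true_ppr, expected_ppr = expected,
           true_tthr = unname(config$true_tthr_effects[profile]),
           adjustable = adjustable, t_event = t_event)
  }) |> bind_rows()

  exact <- config$noise_sd == 0
  lambda_pat <- events$attendance * truth$expected_ppr / 1e4
  if (!exact) {
    noisy <- pmax(truth$expected_ppr + rnorm(nrow(events), 0, config$noise_sd),
                  0.5)
    lambda_pat <- events$attendance * noisy / 1e4
    n_patients <- rpois(nrow(events), lambda_pat)
  } else {
    n_patients <- round(lambda_pat)
  }
  # a registered event always has a handful of encounter forms
  n_patients <- pmax(n_patients, 3L)
  lambda_tr <- events$attendance * truth$true_tthr / 1e4
  n_transfers <- if (exact) round(lambda_tr) else rpois(nrow(events), lambda_tr)
  n_transfers <- pmin(n_transfers, n_patients)

  encounters <- purrr::map(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    np <- n_patients[i]
    if (np == 0) return(NULL)
    days <- seq(ev$first_day, by = "day", length.out = ev$n_days)
    ages <- draw_ages(np, ev$age_profile)
    age_missing <- runif(np) < config$missing_age_rate
    age_missing[1] <- FALSE  # age class stays computable for every event
    ages[age_missing] <- NA_real_
    nt <- n_transfers[i]
    dism <- c(rep("hospital_by_ambulance", nt),
              sample(c("back_to_event", "own_means", "other"), np - nt,
                     replace = TRUE, prob = c(0.92, 0.05, 0.03)))
    # missingness hits the routine destinations, never recorded transfers
    mask <- c(rep(FALSE, nt), runif(np - nt) < config$missing_dismissal_rate)
    dism[mask] <- NA_character_
    tibble(
      event_id = ev$event_id,
      day = days[sample.int(length(days), np, replace = TRUE)],
      age = round(ages, 0),
      dismissal = dism,
      triage = sample(c("green", "yellow", "red"), np, replace = TRUE,
                      prob = c(0.9, 0.08, 0.02))
    )
  }) |> bind_rows()

  events_out <- events |>
    select("event_id", "series_name", "year", "category", "attendance",
           "first_day", "n_days", "timing", "indoor", "bounded", "camping",
           "alcohol", "hospital_distance_km", "hospital_time_min",
           "sold_out")

  truth_attrs <- truth
  attr(truth_attrs, "true_effects") <- config$true_effects
  attr(truth_attrs, "true_tthr_effects") <- config$true_tthr_effects
  attr(truth_attrs, "temp_slope") <- config$temp_slope
  attr(truth_attrs, "temp_pivot") <- config$temp_pivot
  attr(truth_attrs, "reference_ppr") <- config$reference_ppr

  structure(list(events = events_out, encounters = encounters,
                 temperatures = temperatures, ground_truth = truth_attrs,
                 config = config),
            class = "mur_registry")
}

#' Write a synthetic registry to CSV files
#'
#' Writes `events.csv`, `encounters.csv` and `temperatures.csv` matching
#' the [read_events()] / [read_encounters()] / [read_temperatures()]
#' schemas.
#'
#' @param registry A `mur_registry`.
#' @param dir Destination directory (created if needed).
#' @return The paths, invisibly.
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("events.csv", "encounters.csv",
                            "temperatures.csv"))
  readr::write_csv(registry$events, paths[1], progress = FALSE)
  readr::write_csv(registry$encounters, paths[2], progress = FALSE)
  readr::write_csv(registry$temperatures, paths[3], progress = FALSE)
  invisible(paths)
}

#' Generate day-level records of the reference multi-day event
#'
#' 9 editions x 4 days = 36 day-level records with daily attendance and
#' temperatures, where daily PPR follows the configured linear law
#' `reference_ppr + slope * (T - pivot)` plus day-level noise, and daily
#' TTHR is flat in temperature (the null the association check is expected
#' to confirm).
#'
#' @param config A [synth_config()]; `temp_which` selects the generating
#'   covariate, `ref_noise_sd` the day-level PPR noise.
#' @param n_editions,days_per_edition Layout of the reference series.
#' @return Tibble with `edition_year`, `day_index`, `attendance_day`,
#'   `t_av`, `t_max`, `ppr_day`, `tthr_day`.
#' @export
generate_reference_daily <- function(config = synth_config(),
                                     n_editions = 9L,
                                     days_per_edition = 4L) {
  with_preserved_seed(config$seed + 1L, {
    n <- n_editions * days_per_edition
    tcol <- config$temp_which
    t_main <- round(runif(n, 18, 33), 1)
    if (tcol == "t_max") {
      t_max <- t_main
      t_av <- round(t_max - 5.2 + rnorm(n, 0, 1), 1)
    } else {
      t_av <- t_main
      t_max <- round(t_av + 5.2 + rnorm(n, 0, 1), 1)
    }
    intercept <- config$reference_ppr - config$temp_slope * config$temp_pivot
    ppr <- intercept + config$temp_slope * t_main +
      rnorm(n, 0, config$ref_noise_sd)
    tibble(
      edition_year = rep(config$first_year + seq_len(n_editions) - 1L,
                         each = days_per_edition),
      day_index = rep(seq_len(days_per_edition), n_editions),
      attendance_day = round(runif(n, 80000, 90000), -2),
      t_av = round(t_av, 1), t_max = round(t_max, 1),
      ppr_day = pmax(ppr, 0),
      tthr_day = pmax(1.7 + rnorm(n, 0, 0.8), 0)
    )
  })
}

#' Assess ground-truth recovery of a fitted tree
#'
#' Compares a fitted tree's leaf partition with the generating
#' piecewise-constant structure of a synthetic registry. The structure
#' counts as recovered when no leaf mixes events from profiles with
#' different true rates (every generating split is realized; extra splits
#' refining a true group are allowed). Leaf means are compared with the
#' mean generating expectation of the leaf's events, in units of the leaf's
#' standard error.
#'
#' @param tree A fitted `mur_tree`.
#' @param aggregated The aggregated event table the tree was fitted on.
#' @param ground_truth The registry's `ground_truth` tibble; `truth_col`
#'   names the expected-value column (`"expected_ppr"` for PPR trees).
#' @param truth_col Column of `ground_truth` holding per-event expectations.
#' @param group_col Column holding the true-rate group (default the profile
#'   true rate, so profiles sharing a rate may legitimately share a leaf).
#' @return A list: `structure_recovered`, `means_within_2se`, `recovered`
#'   (both), and the per-leaf comparison `table`.
#' @export
recovery_report <- function(tree, aggregated, ground_truth,
                            truth_col = "expected_ppr",
                            group_col = "true_ppr") {
  routed <- predict(tree, aggregated)
  tab <- tibble(
    event_id = aggregated$event_id,
    leaf = routed$node_id,
    pred = routed$pred
  ) |>
    left_join(ground_truth, by = "event_id")
  purity <- tab |>
    group_by(.data$leaf) |>
    summarise(n_groups = dplyr::n_distinct(.data[[group_col]]),
              .groups = "drop")
  leaf_tab <- tab |>
    group_by(.data$leaf) |>
    summarise(
      n = dplyr::n(),
      leaf_mean = first(.data$pred),
      truth_mean = mean(.data[[truth_col]]),
      obs_sd = sd(.data[[truth_col]]),
      .groups = "drop"
    )
  # leaf SE from the tree's own training spread
  leaf_sd <- vapply(leaf_tab$leaf, function(id)
    tree$nodes[[as.character(id)]]$sd, numeric(1))
  leaf_tab$se <- leaf_sd / sqrt(leaf_tab$n)
  leaf_tab$within_2se <- abs(leaf_tab$leaf_mean - leaf_tab$truth_mean) <=
    pmax(2 * leaf_tab$se, 1e-8)
  list(
    structure_recovered = all(purity$n_groups == 1),
    means_within_2se = all(leaf_tab$within_2se),
    recovered = all(purity$n_groups == 1) && all(leaf_tab$within_2se),
    table = leaf_tab
  )
}

#' Deterministically corrupt a registry to exercise error paths
#'
#' Schemes: `attendance_gap` blanks one interior attendance value in the
#' first series with at least three editions; `sold_out_chain` marks a
#' series sold out and blanks every attendance after the first edition;
#' `date_leakage` adds encounters dated the day before the first and the
#' day after the last official day of the first three events (which outcome
#' construction must exclude).
#'
#' @param registry A `mur_registry`.
#' @param scheme One of `"attendance_gap"`, `"sold_out_chain"`,
#'   `"date_leakage"`.
#' @return The corrupted registry; `$manifest` lists what was altered.
#' @export
corrupt_for_robustness <- function(registry,
                                   scheme = c("attendance_gap",
                                              "sold_out_chain",
                                              "date_leakage")) {
  scheme <- tryCatch(match.arg(scheme), error = function(e) {
    mur_stop(sprintf("Unknown corruption scheme '%s'.", scheme[1]),
             class = "murtree_error_config")
  })
  ev <- registry$events
  manifest <- tibble(scheme = character(0), event_id = character(0),
                     action = character(0))
  if (scheme == "attendance_gap") {
    sizes <- table(ev$series_name)
    target <- names(sizes)[sizes >= 3][1]
    rows <- which(ev$series_name == target)
    rows <- rows[order(ev$year[rows])]
    mid <- rows[2]
    ev$attendance[mid] <- NA
    manifest <- tibble(scheme = scheme, event_id = ev$event_id[mid],
                       action = "attendance set to missing (interior gap)")
  } else if (scheme == "sold_out_chain") {
    sizes <- table(ev$series_name)
    target <- names(sizes)[sizes >= 3][1]
    rows <- which(ev$series_name == target)
    rows <- rows[order(ev$year[rows])]
    ev$sold_out[rows] <- TRUE
    later <- rows[-1]
    ev$attendance[later] <- NA
    manifest <- tibble(scheme = scheme, event_id = ev$event_id[later],
                       action = "sold out, attendance missing")
  } else {
    targets <- ev$event_id[seq_len(min(3, nrow(ev)))]
    extra <- purrr::map(targets, function(id) {
      row <- ev[ev$event_id == id, ]
      days <- official_days_of(row)
      tibble(event_id = id,
             day = c(days[1] - 1, days[length(days)] + 1),
             age = c(25, 30),
             dismissal = c("back_to_event", "back_to_event"),
             triage = c("green", "green"))
    }) |> bind_rows()
    registry$encounters <- bind_rows(registry$encounters, extra)
    manifest <- tibble(scheme = scheme, event_id = targets,
                       action = "pre/post-day encounters added")
  }
  registry$events <- ev
  registry$manifest <- manifest
  registry
}
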