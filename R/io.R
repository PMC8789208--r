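# Delimited-text I/O for the registry tables. All tables are plain CSV with
# ISO dates and true/false booleans; enum columns are validated on read and
# a schema error names the offending row and column.

#' Read the event-edition table
#'
#' Expected columns: `event_id`, `series_name`, `year`, `category`,
#' `attendance`, `first_day` (ISO date of the first official day), `n_days`,
#' `timing`, `indoor`, `bounded`, `camping`, `alcohol`,
#' `hospital_distance_km`, `hospital_time_min`, `sold_out`. `attendance` may
#' be empty (resolved later by [impute_attendance()]).
#'
#' @param path Path to a CSV file.
#' @return Tibble of event editions with validated enum columns.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          event_id = readr::col_character(),
                          series_name = readr::col_character(),
                          year = readr::col_integer(),
                          category = readr::col_character(),
                          attendance = readr::col_double(),
                          first_day = readr::col_date(),
                          n_days = readr::col_integer(),
                          timing = readr::col_character(),
                          indoor = readr::col_logical(),
                          bounded = readr::col_logical(),
                          camping = readr::col_logical(),
                          alcohol = readr::col_character(),
                          hospital_distance_km = readr::col_double(),
                          hospital_time_min = readr::col_double(),
                          sold_out = readr::col_logical()
                        ))
  ev$category <- check_enum(as.character(ev$category), "category", "events")
  ev$timing <- check_enum(as.character(ev$timing), "timing", "events")
  ev$alcohol <- check_enum(as.character(ev$alcohol), "alcohol", "events")
  bad_att <- which(!is.na(ev$attendance) & ev$attendance <= 0)
  if (length(bad_att) > 0) {
    mur_stop(sprintf("Non-positive attendance in events (row %d).", bad_att[1]),
             class = "murtree_error_schema")
  }
  ev
}

#' Read the patient-encounter table
#'
#' Expected columns: `event_id`, `day` (ISO date), `age` (years, may be
#' empty), `dismissal` (one of `back_to_event`, `hospital_by_ambulance`,
#' `own_means`, `other`, or empty), `triage` (free label, carried but unused
#' by the models).
#'
#' @param path Path to a CSV file.
#' @return Tibble of patient encounter forms.
#' @export
read_encounters <- function(path) {
  enc <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           event_id = readr::col_character(),
                           day = readr::col_date(),
                           age = readr::col_double(),
                           dismissal = readr::col_character(),
                           triage = readr::col_character()
                         ))
  enc$dismissal <- as.character(check_enum(as.character(enc$dismissal),
                                           "dismissal", "encounters"))
  bad_age <- which(!is.na(enc$age) & (enc$age < 0 | enc$age > 120))
  if (length(bad_age) > 0) {
    mur_stop(sprintf("Age out of [0, 120] in encounters (row %d).", bad_age[1]),
             class = "murtree_error_schema")
  }
  enc
}

#' Read the daily temperature table
#'
#' Expected columns: `day` (ISO date), `t_av_c` (24 h average, Celsius),
#' `t_max_c` (daily maximum, Celsius).
#'
#' @param path Path to a CSV file.
#' @return Tibble of daily temperatures.
#' @export
read_temperatures <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    day = readr::col_date(),
                    t_av_c = readr::col_double(),
                    t_max_c = readr::col_double()
                  ))
}

#' Write / read the aggregated event-level analysis table
#'
#' Round-trip stable: writing an [aggregate_events()] result and reading it
#' back reproduces the table (factor columns restored with their canonical
#' levels).
#'
#' @param aggregated Tibble from [aggregate_events()].
#' @param path Destination CSV path.
#' @return `write_aggregated()` returns `aggregated` invisibly;
#'   `read_aggregated()` returns the tibble.
#' @export
write_aggregated <- function(aggregated, path) {
  readr::write_csv(aggregated, path, progress = FALSE)
  invisible(aggregated)
}

#' @rdname write_aggregated
#' @export
read_aggregated <- function(path) {
  agg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           event_id = readr::col_character(),
                           series_name = readr::col_character(),
                           first_day = readr::col_date(),
                           .default = readr::col_guess()
                         ))
  agg |>
    mutate(
      category = check_enum(as.character(.data$category), "category",
                            "aggregated"),
      timing = check_enum(as.character(.data$timing), "timing", "aggregated"),
      alcohol = check_enum(as.character(.data$alcohol), "alcohol",
                           "aggregated"),
      attendance_class = factor(.data$attendance_class,
                                levels = mur_levels$attendance_class,
                                ordered = TRUE),
      age_class = factor(.data$age_class, levels = mur_levels$age_class),
      days_class = factor(.data$days_class, levels = mur_levels$days_class,
                          ordered = TRUE)
    )
}
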