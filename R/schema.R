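# Controlled vocabularies for the registry tables. Level order is the order
# used for tie-breaking in the tree engine and for ordered-factor cut points.

#' Controlled vocabularies for registry tables
#'
#' Level sets for the categorical fields of the event and encounter tables.
#' `attendance_class` and `days_class` are ordered; the remaining enums are
#' nominal. The six event categories follow the mass-gathering taxonomy used
#' by the Belgian Red Cross registry this package models: city festivals,
#' indoor/outdoor electronic dance music (EDM), indoor dance, outdoor music
#' and active recreational sports events.
#'
#' @format A named list of character vectors.
#' @export
mur_levels <- list(
  category   = c("city_festival", "indoor_edm", "indoor_dance",
                 "outdoor_edm", "outdoor_music", "sports_event"),
  timing     = c("day", "night", "day_and_night"),
  alcohol    = c("none", "limited", "unlimited"),
  dismissal  = c("back_to_event", "hospital_by_ambulance", "own_means", "other"),
  attendance_class = c("lt10k", "a10_20k", "a20_30k", "a30_100k",
                       "a100k_1M", "gt1M"),
  age_class  = c("children", "young_adults", "middle_adults", "mixed_family"),
  days_class = c("d1", "d2", "d3plus"),
  hospital_distance_class = c("d_le5km", "d_5_15km", "d_gt15km"),
  hospital_time_class     = c("t_le10min", "t_10_20min", "t_gt20min")
)

# Event-level predictors entered in the PPR tree, in declared order.
# Declared order breaks ties between equally good splits.
mur_base_predictors <- c("category", "attendance_class", "age_class",
                         "days_class", "timing", "indoor", "bounded",
                         "camping", "alcohol")

# Which predictors are ordered (only order-respecting cuts are searched).
mur_ordered_predictors <- c("attendance_class", "days_class",
                            "hospital_distance_class", "hospital_time_class")

mur_stop <- function(msg, class, ...) {
  abort(msg, class = c(class, "murtree_error"), ...)
}

# Reporting convention: round half away from zero (rates are displayed to
# 1 decimal; full precision is kept internally).
#' Round half away from zero
#'
#' Rounding used when reporting rates to a fixed number of decimals; ties are
#' rounded away from zero rather than to even, matching how per-10,000 rates
#' are conventionally displayed.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_report <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_enum <- function(x, field, table_name, extra_levels = character()) {
  levels_ok <- c(mur_levels[[field]], extra_levels)
  bad <- which(!is.na(x) & !(x %in% levels_ok))
  if (length(bad) > 0) {
    mur_stop(
      sprintf("Invalid value '%s' for column '%s' in %s (row %d).",
              x[bad[1]], field, table_name, bad[1]),
      class = "murtree_error_schema"
    )
  }
  factor(x, levels = mur_levels[[field]])
}
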