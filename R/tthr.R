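# Cascaded TTHR model: the fitted PPR tree's terminal node joins hospital
# proximity and the nine base predictors as candidates for a second
# regression tree. Predicted PPR enters as the categorical terminal-node id
# (not the numeric leaf mean), matching how published TTHR trees label their
# splits by PPR-model node numbers. TTHR predictions are never
# temperature-adjusted: daily transfer rates show no temperature association
# on the reference event.

#' Bin hospital proximity into ordered classes
#'
#' The tree engine takes categorical predictors, so the continuous distance
#' and driving time to the nearest hospital are binned into three ordered
#' classes each. Default bins: distance <= 5, 5–15, > 15 km; time <= 10,
#' 10–20, > 20 min (boundaries inclusive on the left class).
#'
#' @param km,minutes Numeric vectors.
#' @param breaks Two inner cut points (overridable).
#' @return Ordered factors.
#' @export
bin_hospital_distance <- function(km, breaks = c(5, 15)) {
  cut(km, breaks = c(-Inf, breaks, Inf),
      labels = mur_levels$hospital_distance_class,
      right = TRUE, ordered_result = TRUE)
}

#' @rdname bin_hospital_distance
#' @export
bin_hospital_time <- function(minutes, breaks = c(10, 20)) {
  cut(minutes, breaks = c(-Inf, breaks, Inf),
      labels = mur_levels$hospital_time_class,
      right = TRUE, ordered_result = TRUE)
}

# candidate predictors of the TTHR tree, in declared order
mur_tthr_predictors <- c(mur_base_predictors, "ppr_node",
                         "hospital_distance_class", "hospital_time_class")

#' Build the TTHR candidate-feature table
#'
#' Routes every event through the fitted (unadjusted) PPR tree and attaches
#' its terminal node id (`ppr_node`, categorical) and that node's mean PPR
#' (`ppr_pred`, informational), plus binned hospital distance and time —
#' giving 12 candidate predictors per event: the 9 base predictors,
#' `ppr_node`, `hospital_distance_class` and `hospital_time_class`.
#'
#' @param events Aggregated, categorized event table (see
#'   [aggregate_events()]) including `hospital_distance_km` and
#'   `hospital_time_min`.
#' @param ppr_tree The fitted PPR `mur_tree`.
#' @param distance_breaks,time_breaks Inner cut points passed to the binning
#'   helpers.
#' @return The events tibble with `ppr_node`, `ppr_pred`,
#'   `hospital_distance_class`, `hospital_time_class` added.
#' @export
build_tthr_features <- function(events, ppr_tree,
                                distance_breaks = c(5, 15),
                                time_breaks = c(10, 20)) {
  routed <- predict(ppr_tree, events)
  terminal_ids <- sort(vapply(
    purrr::keep(ppr_tree$nodes, ~ is.null(.x$split)),
    `[[`, integer(1), "id"))
  events |>
    mutate(
      ppr_node = factor(routed$node_id, levels = terminal_ids),
      ppr_pred = routed$pred,
      hospital_distance_class =
        bin_hospital_distance(.data$hospital_distance_km, distance_breaks),
      hospital_time_class =
        bin_hospital_time(.data$hospital_time_min, time_breaks)
    )
}

#' Fit the TTHR regression tree
#'
#' Same engine and grid-search protocol as the PPR model, applied to the
#' TTHR outcome over the 12 candidate predictors from
#' [build_tthr_features()]. No temperature adjustment is ever applied to
#' TTHR predictions.
#'
#' @param features Output of [build_tthr_features()].
#' @param minsplit_range,maxdepth_range,cp,minbucket,n_folds,seed Grid
#'   search settings, defaulting to the same 128-point grid as the PPR
#'   model.
#' @return The selected `mur_tree` for TTHR.
#' @export
fit_tthr <- function(features, minsplit_range = 5:20, maxdepth_range = 8:15,
                     cp = 0.01, minbucket = 1L, n_folds = 10L, seed = 1L) {
  grid_search(features, outcome = "tthr",
              predictors = mur_tthr_predictors,
              minsplit_range = minsplit_range,
              maxdepth_range = maxdepth_range,
              cp = cp, minbucket = minbucket, n_folds = n_folds, seed = seed)
}
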