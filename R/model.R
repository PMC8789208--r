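# The full model bundle: PPR tree, temperature-transfer parameters, TTHR
# tree, and the evidence for not adjusting TTHR. `validate()` applies a
# fitted bundle to a categorized dataset without refitting.

#' Fit the full medical-usage prediction model
#'
#' Development pipeline: (1) grid-searched PPR regression tree over the nine
#' base predictors; (2) daily linear temperature fits on the reference
#' event's day-level records, converted to transfer parameters anchored at
#' the reference event's tree-predicted PPR; (3) temperature-association
#' check for daily TTHR (expected verdict: not associated, so TTHR is never
#' adjusted); (4) grid-searched TTHR tree over the 12 candidate predictors,
#' including the PPR tree's terminal node.
#'
#' @param aggregated Aggregated, categorized development table from
#'   [aggregate_events()] (needs `ppr`, `tthr`, predictors and hospital
#'   proximity columns).
#' @param daily_reference Day-level records of the reference multi-day event
#'   with columns `ppr_day`, `t_av`, `t_max` and optionally `tthr_day`.
#'   `NULL` skips the temperature stage.
#' @param reference_event_id Event id (in `aggregated`) whose tree-predicted
#'   PPR anchors the temperature transfer. Defaults to the adjustable
#'   (outdoor June–September) event with the highest tree-predicted PPR —
#'   the large multi-day festival archetype the day-level reference data
#'   describe; anchoring at a low-rate event would misplace the pivot and
#'   inflate every transferred correction.
#' @param minsplit_range,maxdepth_range,cp,n_folds,seed Grid-search settings
#'   shared by both trees.
#' @param distance_breaks,time_breaks Hospital proximity bins.
#' @return A `mur_model` list: `ppr_tree`, `tthr_tree`, `adj_tav`,
#'   `adj_tmax`, `tthr_temp_tav`, `tthr_temp_tmax`, `reference_event_id`,
#'   breaks and the EPV table.
#' @export
fit_mur_model <- function(aggregated, daily_reference = NULL,
                          reference_event_id = NULL,
                          minsplit_range = 5:20, maxdepth_range = 8:15,
                          cp = 0.01, n_folds = 10L, seed = 1L,
                          distance_breaks = c(5, 15),
                          time_breaks = c(10, 20)) {
  ppr_tree <- grid_search(aggregated, outcome = "ppr",
                          predictors = mur_base_predictors,
                          minsplit_range = minsplit_range,
                          maxdepth_range = maxdepth_range,
                          cp = cp, n_folds = n_folds, seed = seed)

  adj_tav <- adj_tmax <- NULL
  tthr_temp_tav <- tthr_temp_tmax <- NULL
  if (!is.null(daily_reference)) {
    if (is.null(reference_event_id)) {
      adjustable <- vapply(seq_len(nrow(aggregated)),
                           function(i) is_adjustable(aggregated[i, ]),
                           logical(1))
      cand <- aggregated[adjustable, ]
      if (nrow(cand) == 0) {
        mur_stop("No adjustable event to anchor the temperature transfer.",
                 class = "murtree_error_domain")
      }
      cand_pred <- predict(ppr_tree, cand)$pred
      top <- which(cand_pred >= max(cand_pred) - 1e-9)
      reference_event_id <- cand$event_id[top[which.max(cand$attendance[top])]]
    }
    ref_row <- aggregated[aggregated$event_id == reference_event_id, ]
    ref_ppr <- predict(ppr_tree, ref_row)$pred[1]
    adj_tav <- derive_adjustment(fit_daily_linear(daily_reference, "t_av"),
                                 ref_ppr)
    adj_tmax <- derive_adjustment(fit_daily_linear(daily_reference, "t_max"),
                                  ref_ppr)
    if (!is.null(daily_reference$tthr_day)) {
      tthr_daily <- daily_reference |> mutate(ppr_day = .data$tthr_day)
      tthr_temp_tav <- check_temperature_association(tthr_daily, "t_av")
      tthr_temp_tmax <- check_temperature_association(tthr_daily, "t_max")
    }
  }

  features <- build_tthr_features(aggregated, ppr_tree,
                                  distance_breaks, time_breaks)
  tthr_tree <- fit_tthr(features, minsplit_range, maxdepth_range,
                        cp = cp, n_folds = n_folds, seed = seed)

  structure(list(
    ppr_tree = ppr_tree,
    tthr_tree = tthr_tree,
    adj_tav = adj_tav,
    adj_tmax = adj_tmax,
    tthr_temp_tav = tthr_temp_tav,
    tthr_temp_tmax = tthr_temp_tmax,
    reference_event_id = reference_event_id,
    distance_breaks = distance_breaks,
    time_breaks = time_breaks,
    epv = bind_rows(
      compute_epv(nrow(aggregated), length(mur_base_predictors)) |>
        mutate(outcome = "ppr", .before = 1),
      compute_epv(nrow(aggregated), length(mur_tthr_predictors)) |>
        mutate(outcome = "tthr", .before = 1)
    )
  ), class = "mur_model")
}

#' @export
print.mur_model <- function(x, ...) {
  cat("Medical-usage prediction model\n")
  cat(sprintf("  PPR tree: %d terminal nodes, xerror %.3f, R2(train) %.2f\n",
              x$ppr_tree$n_terminal, x$ppr_tree$xerror, x$ppr_tree$r2_train))
  cat(sprintf("  TTHR tree: %d terminal nodes, xerror %.3f, R2(train) %.2f\n",
              x$tthr_tree$n_terminal, x$tthr_tree$xerror,
              x$tthr_tree$r2_train))
  if (!is.null(x$adj_tmax)) {
    cat(sprintf("  T_max transfer: slope %.1f PPR/degC, pivot %.1f C, reference PPR %.0f\n",
                x$adj_tmax$slope_b, x$adj_tmax$pivot_t,
                x$adj_tmax$reference_ppr))
  }
  if (!is.null(x$tthr_temp_tmax)) {
    cat(sprintf("  TTHR vs T_max: %s (p = %.2f) -> TTHR not temperature-adjusted\n",
                if (x$tthr_temp_tmax$associated) "associated"
                else "not associated", x$tthr_temp_tmax$p_slope))
  }
  invisible(x)
}

#' Predict PPR and TTHR for new events from a fitted bundle
#'
#' Pure evaluation: routes events through the serialized trees, applies the
#' temperature transfer to the PPR of adjustable events (outdoor,
#' June–September) when transfer parameters and temperatures are available,
#' and never adjusts TTHR.
#'
#' @param object A `mur_model`.
#' @param newdata Aggregated, categorized event table (same class
#'   definitions as development).
#' @param temperatures Optional daily temperature table (`day`, `t_av_c`,
#'   `t_max_c`) used to compute event-period mean temperatures.
#' @param ... Unused.
#' @return Tibble with `event_id`, `ppr_node`, `ppr_crude`, `ppr_tav`,
#'   `ppr_tmax` (NA when no transfer parameters/temperature), `tthr_node`,
#'   `tthr_pred`.
#' @export
predict.mur_model <- function(object, newdata, temperatures = NULL, ...) {
  crude <- predict(object$ppr_tree, newdata)
  adjust_variant <- function(params, which) {
    if (is.null(params)) return(rep(NA_real_, nrow(newdata)))
    vapply(seq_len(nrow(newdata)), function(i) {
      ev <- newdata[i, ]
      if (!is_adjustable(ev)) return(crude$pred[i])
      tcol <- paste0(which, "_event")
      temp <- if (!is.null(newdata[[tcol]])) newdata[[tcol]][i]
              else if (!is.null(temperatures))
                event_temperature(ev, temperatures, which)
              else NA_real_
      adjust_ppr(crude$pred[i], temp, params, ev)
    }, numeric(1))
  }
  features <- build_tthr_features(newdata, object$ppr_tree,
                                  object$distance_breaks, object$time_breaks)
  tthr <- predict(object$tthr_tree, features)
  tibble(
    event_id = newdata$event_id,
    ppr_node = crude$node_id,
    ppr_crude = crude$pred,
    ppr_tav = adjust_variant(object$adj_tav, "t_av"),
    ppr_tmax = adjust_variant(object$adj_tmax, "t_max"),
    tthr_node = tthr$node_id,
    tthr_pred = tthr$pred
  )
}

#' Validate a fitted bundle on a dataset
#'
#' Applies the serialized model to a categorized dataset (no refitting) and
#' builds calibration reports — R^2 with confidence interval and
#' deviation-band counts — for crude, T_av-adjusted and T_max-adjusted PPR
#' (when transfer parameters exist) and for TTHR (never adjusted).
#'
#' @param model A `mur_model`.
#' @param dataset Aggregated, categorized event table with observed `ppr`
#'   and `tthr`.
#' @param mode `"development"`, `"temporal"` or `"external"` (label only).
#' @param temperatures Optional daily temperature table.
#' @param level,band Report settings (see [calibration_report] fields).
#' @return A `mur_validation` list: `ppr` (named list of `mur_calibration`
#'   per variant) and `tthr`.
#' @export
validate <- function(model, dataset,
                     mode = c("development", "temporal", "external"),
                     temperatures = NULL, level = 0.95, band = 0.25) {
  mode <- match.arg(mode)
  preds <- predict(model, dataset, temperatures = temperatures)
  ppr_reports <- list(
    crude = calibration_report(dataset$ppr, preds$ppr_crude, level, band,
                               variant = "crude", mode = mode)
  )
  if (!all(is.na(preds$ppr_tav))) {
    ppr_reports$t_av <- calibration_report(dataset$ppr, preds$ppr_tav,
                                           level, band, variant = "t_av",
                                           mode = mode)
  }
  if (!all(is.na(preds$ppr_tmax))) {
    ppr_reports$t_max <- calibration_report(dataset$ppr, preds$ppr_tmax,
                                            level, band, variant = "t_max",
                                            mode = mode)
  }
  structure(list(
    ppr = ppr_reports,
    tthr = calibration_report(dataset$tthr, preds$tthr_pred, level, band,
                              variant = "crude", mode = mode),
    mode = mode,
    predictions = preds
  ), class = "mur_validation")
}

#' @export
print.mur_validation <- function(x, ...) {
  for (rep in x$ppr) {
    cat("PPR "); print(rep)
  }
  cat("TTHR "); print(x$tthr)
  invisible(x)
}

#' @method glance mur_validation
#' @export
glance.mur_validation <- function(x, ...) {
  bind_rows(
    purrr::map(x$ppr, glance) |> bind_rows() |>
      mutate(outcome = "ppr", .before = 1),
    glance(x$tthr) |> mutate(outcome = "tthr", .before = 1)
  )
}

#' Persist / restore a fitted bundle as JSON text
#'
#' @param model A `mur_model`.
#' @param path Destination file.
#' @return `mur_save_model()` returns `model` invisibly; `mur_load_model()`
#'   the restored `mur_model`.
#' @export
mur_save_model <- function(model, path) {
  obj <- list(
    format = "murtree-model/1",
    ppr_tree = jsonlite::fromJSON(tree_to_json(model$ppr_tree),
                                  simplifyVector = FALSE),
    tthr_tree = jsonlite::fromJSON(tree_to_json(model$tthr_tree),
                                   simplifyVector = FALSE),
    adj_tav = if (!is.null(model$adj_tav)) unclass(model$adj_tav),
    adj_tmax = if (!is.null(model$adj_tmax)) unclass(model$adj_tmax),
    tthr_temp_tav = if (!is.null(model$tthr_temp_tav))
      unclass(model$tthr_temp_tav),
    tthr_temp_tmax = if (!is.null(model$tthr_temp_tmax))
      unclass(model$tthr_temp_tmax),
    reference_event_id = model$reference_event_id,
    distance_breaks = model$distance_breaks,
    time_breaks = model$time_breaks
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null", pretty = TRUE),
             path)
  invisible(model)
}

#' @rdname mur_save_model
#' @export
mur_load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "murtree-model/1")) {
    mur_stop("Not a serialized murtree model bundle.",
             class = "murtree_error_schema")
  }
  restore_adj <- function(a) {
    if (is.null(a)) return(NULL)
    adjustment_params(a$slope_b, a$pivot_t, a$reference_ppr, a$which)
  }
  restore_fit <- function(f) {
    if (is.null(f)) return(NULL)
    structure(f, class = "mur_linfit")
  }
  structure(list(
    ppr_tree = tree_from_json(jsonlite::toJSON(obj$ppr_tree,
                                               auto_unbox = TRUE,
                                               digits = NA, null = "null")),
    tthr_tree = tree_from_json(jsonlite::toJSON(obj$tthr_tree,
                                                auto_unbox = TRUE,
                                                digits = NA, null = "null")),
    adj_tav = restore_adj(obj$adj_tav),
    adj_tmax = restore_adj(obj$adj_tmax),
    tthr_temp_tav = restore_fit(obj$tthr_temp_tav),
    tthr_temp_tmax = restore_fit(obj$tthr_temp_tmax),
    reference_event_id = obj$reference_event_id,
    distance_breaks = unlist(obj$distance_breaks),
    time_breaks = unlist(obj$time_breaks)
  ), class = "mur_model")
}
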