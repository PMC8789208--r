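# Linear temperature adjustment of tree-predicted PPR. The daily linear
# PPR–temperature relationship is fitted on a reference multi-day event (the
# only one with daily attendance, hence daily PPR) and transferred
# proportionally to other events:
#
#   PPR_adj = PPR_tree + (PPR_tree / PPR_ref) * b * (T - T_pivot)
#
# where b is the fitted slope, PPR_ref the tree-predicted PPR of the
# reference event and T_pivot the temperature at which the fitted line
# passes through PPR_ref (so at the pivot the adjustment vanishes). The
# adjustment applies to outdoor events held entirely in June–September.

#' Fit the daily linear temperature–PPR relationship
#'
#' Ordinary least squares of daily PPR on daily temperature (24 h average or
#' daily maximum) over the day-level records of a reference event.
#'
#' @param observations Data frame of daily records with columns `ppr_day`
#'   and the chosen temperature column.
#' @param which `"t_av"` (24 h average) or `"t_max"` (daily maximum).
#' @return A `mur_linfit` list: `intercept`, `slope` (PPR per degree C),
#'   `n`, `p_slope` (two-sided), `r2`, `which`.
#' @export
fit_daily_linear <- function(observations, which = c("t_av", "t_max")) {
  which <- match.arg(which)
  tcol <- observations[[which]]
  y <- observations$ppr_day
  if (length(y) < 3) {
    mur_stop("Need at least 3 day-level observations.",
             class = "murtree_error_domain")
  }
  if (length(unique(tcol)) < 2) {
    mur_stop("Temperature is constant: slope undefined.",
             class = "murtree_error_fit_undefined")
  }
  if (var(y) == 0) {
    # flat outcome: zero slope, no association
    return(structure(list(intercept = mean(y), slope = 0, n = length(y),
                          p_slope = 1, r2 = 0, which = which),
                     class = "mur_linfit"))
  }
  fit <- lm(y ~ tcol)
  # summary.lm warns on noiseless data; the sigma == 0 branch handles it
  sm <- suppressWarnings(summary(fit))
  slope_row <- sm$coefficients["tcol", ]
  structure(list(
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    n = length(y),
    p_slope = if (sm$sigma == 0) 0 else unname(slope_row["Pr(>|t|)"]),
    r2 = sm$r.squared,
    which = which
  ), class = "mur_linfit")
}

#' @method tidy mur_linfit
#' @export
tidy.mur_linfit <- function(x, ...) {
  tibble(term = c("(Intercept)", x$which),
         estimate = c(x$intercept, x$slope))
}

#' @method glance mur_linfit
#' @export
glance.mur_linfit <- function(x, ...) {
  tibble(n = x$n, slope = x$slope, intercept = x$intercept,
         p_slope = x$p_slope, r2 = x$r2, which = x$which)
}

#' Derive temperature-transfer parameters from a daily fit
#'
#' Converts the fitted line into the transfer form used to adjust any
#' event's tree-predicted PPR: the slope is carried over and the pivot
#' temperature is the temperature at which the fitted line equals the
#' reference event's tree-predicted PPR,
#' `pivot_t = (reference_ppr - intercept) / slope`.
#'
#' @param fit A `mur_linfit` from [fit_daily_linear()].
#' @param reference_ppr Tree-predicted PPR of the reference event (> 0).
#' @return A `mur_adjustment` list: `slope_b`, `pivot_t`, `reference_ppr`,
#'   `which`.
#' @export
derive_adjustment <- function(fit, reference_ppr) {
  if (fit$slope == 0) {
    mur_stop("Zero slope: pivot temperature undefined.",
             class = "murtree_error_pivot_undefined")
  }
  stopifnot(reference_ppr > 0)
  structure(list(
    slope_b = fit$slope,
    pivot_t = (reference_ppr - fit$intercept) / fit$slope,
    reference_ppr = reference_ppr,
    which = fit$which
  ), class = "mur_adjustment")
}

#' Construct transfer parameters directly
#'
#' For applying published adjustment coefficients without refitting, e.g.
#' slope 10.6 PPR per degree with pivot 20.4 C on the 24 h average, or slope
#' 7.6 with pivot 25.6 C on the daily maximum, both against a reference
#' tree-predicted PPR of 183 per 10,000.
#'
#' @param slope_b Slope in PPR per degree Celsius.
#' @param pivot_t Pivot temperature in Celsius.
#' @param reference_ppr Tree-predicted PPR of the reference event.
#' @param which Temperature variant the parameters refer to.
#' @return A `mur_adjustment` list.
#' @export
adjustment_params <- function(slope_b, pivot_t, reference_ppr,
                              which = c("t_av", "t_max")) {
  stopifnot(reference_ppr > 0)
  structure(list(slope_b = slope_b, pivot_t = pivot_t,
                 reference_ppr = reference_ppr, which = match.arg(which)),
            class = "mur_adjustment")
}

# Is an event eligible for temperature adjustment? Outdoor, with every
# official day in June-September (an event straddling the boundary is not
# adjusted).
is_adjustable <- function(event) {
  if (isTRUE(event$indoor)) return(FALSE)
  days <- official_days_of(event)
  all(as.integer(format(days, "%m")) %in% 6:9)
}

#' Temperature-adjust a tree-predicted PPR
#'
#' Applies the proportional transfer to events that are outdoor and held
#' entirely in June–September; all other events pass through unchanged. The
#' additive correction scales with the event's own tree-predicted PPR
#' relative to the reference event, and the result is floored at 0 (the
#' linear form can go negative at unseasonably low temperatures).
#'
#' @param ppr_tree Tree-predicted PPR of the event.
#' @param temperature Event temperature in Celsius (for multi-day events,
#'   the unweighted mean over official days of the variant in
#'   `params$which`). `NA` for an adjustable event is an error.
#' @param params A `mur_adjustment`.
#' @param event One-row data frame with at least `indoor`, `first_day`,
#'   `n_days`.
#' @return Adjusted PPR per 10,000.
#' @export
adjust_ppr <- function(ppr_tree, temperature, params, event) {
  if (!is_adjustable(event)) return(ppr_tree)
  if (is.na(temperature)) {
    mur_stop(
      sprintf("Missing temperature for adjustable event '%s'.",
              event$event_id %||% "?"),
      class = "murtree_error_adjustment_impossible")
  }
  adj <- ppr_tree + ppr_tree / params$reference_ppr * params$slope_b *
    (temperature - params$pivot_t)
  max(adj, 0)
}

# mean event-period temperature for each event from the daily table
event_temperature <- function(event, temperatures,
                              which = c("t_av", "t_max")) {
  which <- match.arg(which)
  col <- paste0(which, "_c")
  days <- official_days_of(event)
  tt <- temperatures[as.Date(temperatures$day) %in% days, , drop = FALSE]
  if (nrow(tt) < length(days)) return(NA_real_)
  mean(tt[[col]])
}

#' Test the temperature association of a daily outcome
#'
#' Fits the daily linear model and attaches a verdict: the outcome is called
#' temperature-associated when the two-sided slope p-value is below `alpha`.
#' Used to justify not temperature-adjusting TTHR, whose daily rates show no
#' association on the reference event.
#'
#' @inheritParams fit_daily_linear
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A `mur_linfit` with an added logical `associated` and `alpha`.
#' @export
check_temperature_association <- function(observations,
                                          which = c("t_av", "t_max"),
                                          alpha = 0.05) {
  which <- match.arg(which)
  y <- observations$ppr_day
  if (length(unique(y)) < 2) {
    fit <- structure(list(intercept = mean(y), slope = 0,
                          n = length(y), p_slope = 1, r2 = 0, which = which),
                     class = "mur_linfit")
  } else {
    fit <- fit_daily_linear(observations, which)
  }
  fit$associated <- fit$p_slope < alpha
  fit$alpha <- alpha
  fit
}
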