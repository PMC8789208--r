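# Calibration and validation: squared correlation with confidence interval,
# 25% deviation-band accounting, and observed-vs-predicted reporting for
# development, temporal and external datasets.

#' Squared Pearson correlation between observed and predicted values
#'
#' The calibration measure used throughout: R^2 as the square of the
#' correlation coefficient. Note that correlation is affine-invariant, so
#' this R^2 does not measure bias — a model predicting twice the observed
#' value everywhere still scores 1. Deviation bands
#' ([deviation_bands()]) are the bias-sensitive complement.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3).
#' @return Squared correlation in \[0, 1\].
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3) {
    mur_stop("Need >= 3 observed/predicted pairs.",
             class = "murtree_error_domain")
  }
  if (sd(observed) == 0 || sd(predicted) == 0) {
    mur_stop("Constant observed or predicted values: R^2 undefined.",
             class = "murtree_error_degenerate")
  }
  cor(observed, predicted)^2
}

#' Confidence interval for the squared correlation
#'
#' Default method: Fisher z-transform interval on the correlation r, with
#' endpoints squared and clipped to \[0, 1\]. When the r-interval straddles
#' zero the lower bound of the squared interval is 0. Near r^2 = 0 the
#' squared-endpoint interval is conservative; a seeded bootstrap percentile
#' interval (2000 resamples) is available as an alternative.
#'
#' @inheritParams r_squared
#' @param level Confidence level (default 0.95).
#' @param method `"fisher"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return Named numeric vector `c(low, high)` with attribute `method`.
#' @export
r_squared_ci <- function(observed, predicted, level = 0.95,
                         method = c("fisher", "bootstrap"),
                         n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  n <- length(observed)
  if (n < 4) {
    mur_stop("Need >= 4 pairs for a confidence interval.",
             class = "murtree_error_domain")
  }
  r_squared(observed, predicted)  # validates inputs
  r <- cor(observed, predicted)
  if (method == "fisher") {
    if (abs(r) >= 1 - 1e-12) {
      out <- c(low = 1, high = 1)
    } else {
      z <- atanh(r)
      half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
      r_lo <- tanh(z - half)
      r_hi <- tanh(z + half)
      if (r_lo < 0 && r_hi > 0) {
        out <- c(low = 0, high = max(r_lo^2, r_hi^2))
      } else {
        out <- c(low = min(r_lo^2, r_hi^2), high = max(r_lo^2, r_hi^2))
      }
    }
  } else {
    r2s <- with_preserved_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        if (sd(observed[i]) == 0 || sd(predicted[i]) == 0) return(NA_real_)
        cor(observed[i], predicted[i])^2
      }, numeric(1))
    })
    qs <- quantile(r2s, c((1 - level) / 2, 1 - (1 - level) / 2),
                   na.rm = TRUE, names = FALSE)
    out <- c(low = qs[1], high = qs[2])
  }
  out <- pmin(pmax(out, 0), 1)
  attr(out, "method") <- method
  out
}

#' Deviation-band accounting of predictions
#'
#' Flags, for each event, whether the prediction lies within a relative
#' band of the observed outcome (default 25%, boundary inclusive:
#' `|predicted - observed| <= band * observed`), and whether it over- or
#' under-predicts by more than 50%. Events with observed 0 but positive
#' prediction have an undefined ratio; they are excluded from the band
#' counts and reported separately.
#'
#' @inheritParams r_squared
#' @param band Relative half-width of the band (default 0.25).
#' @return A `mur_bands` object: per-event `table` (observed, predicted,
#'   ratio, within, over50, under50, undefined_ratio) plus the counts
#'   `n_events`, `n_within`, `n_over50`, `n_under50`, `n_undefined`.
#' @export
deviation_bands <- function(observed, predicted, band = 0.25) {
  undefined <- observed == 0 & predicted > 0
  tab <- tibble(
    observed = observed,
    predicted = predicted,
    ratio = ifelse(undefined, NA_real_,
                   ifelse(observed == 0, 1, predicted / observed)),
    undefined_ratio = undefined,
    within = !undefined & abs(predicted - observed) <= band * observed,
    over50 = !undefined & predicted > 1.5 * observed,
    under50 = !undefined & predicted < 0.5 * observed
  )
  structure(list(table = tab, band = band,
                 n_events = nrow(tab),
                 n_within = sum(tab$within),
                 n_over50 = sum(tab$over50),
                 n_under50 = sum(tab$under50),
                 n_undefined = sum(undefined)),
            class = "mur_bands")
}

#' @method glance mur_bands
#' @export
glance.mur_bands <- function(x, ...) {
  tibble(n_events = x$n_events, band = x$band, n_within = x$n_within,
         n_over50 = x$n_over50, n_under50 = x$n_under50,
         n_undefined = x$n_undefined)
}

#' @method tidy mur_bands
#' @export
tidy.mur_bands <- function(x, ...) x$table

calibration_report <- function(observed, predicted, level = 0.95,
                               band = 0.25, variant = "crude",
                               mode = "development",
                               ci_method = "fisher", ci_seed = 1L) {
  bands <- deviation_bands(observed, predicted, band)
  r2 <- tryCatch(r_squared(observed, predicted),
                 murtree_error_degenerate = function(e) NA_real_)
  if (is.na(r2)) {
    ci <- c(low = NA_real_, high = NA_real_)
    method <- "not_computable"
  } else {
    ci <- r_squared_ci(observed, predicted, level = level,
                       method = ci_method, seed = ci_seed)
    method <- attr(ci, "method")
  }
  structure(list(
    table = bands$table,
    n_events = bands$n_events,
    r2 = r2, r2_ci_low = unname(ci["low"]), r2_ci_high = unname(ci["high"]),
    r2_method = method, level = level,
    band = band, n_within_25pct = bands$n_within,
    n_over50 = bands$n_over50, n_under50 = bands$n_under50,
    n_undefined = bands$n_undefined,
    variant = variant, mode = mode
  ), class = "mur_calibration")
}

#' @export
print.mur_calibration <- function(x, ...) {
  cat(sprintf("Calibration (%s, %s): n = %d\n", x$mode, x$variant, x$n_events))
  if (is.na(x$r2)) {
    cat("  R^2 not computable (constant observed or predicted values)\n")
  } else {
    cat(sprintf("  R^2 = %.2f (%.0f%% CI %.2f-%.2f, %s)\n", x$r2,
                100 * x$level, x$r2_ci_low, x$r2_ci_high, x$r2_method))
  }
  cat(sprintf("  within %.0f%% band: %d / %d (undefined ratio: %d)\n",
              100 * x$band, x$n_within_25pct,
              x$n_events - x$n_undefined, x$n_undefined))
  invisible(x)
}

#' @method tidy mur_calibration
#' @export
tidy.mur_calibration <- function(x, ...) x$table

#' @method glance mur_calibration
#' @export
glance.mur_calibration <- function(x, ...) {
  tibble(mode = x$mode, variant = x$variant, n_events = x$n_events,
         r2 = x$r2, r2_ci_low = x$r2_ci_low, r2_ci_high = x$r2_ci_high,
         n_within_25pct = x$n_within_25pct, n_over50 = x$n_over50,
         n_under50 = x$n_under50, n_undefined = x$n_undefined)
}
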