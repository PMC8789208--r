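# Daily linear temperature fit, transfer parameters, PPR adjustment.

daily_obs <- function(t, ppr, which = "t_av") {
  out <- tibble::tibble(ppr_day = ppr)
  out[[which]] <- t
  out
}

test_that("fit_daily_linear recovers exact lines and degenerate cases", {
  obs <- daily_obs(t = c(10, 15, 20, 25), ppr = 5 + 2 * c(10, 15, 20, 25))
  fit <- fit_daily_linear(obs, "t_av")
  expect_equal(fit$slope, 2.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 5.0, tolerance = 1e-12)
  expect_equal(fit$r2, 1.0)

  flat <- daily_obs(t = c(10, 15, 20), ppr = rep(30, 3))
  ffit <- fit_daily_linear(flat, "t_av")
  expect_equal(ffit$slope, 0.0)
  expect_equal(ffit$r2, 0.0)

  const_t <- daily_obs(t = rep(20, 4), ppr = c(1, 2, 3, 4))
  expect_error(fit_daily_linear(const_t, "t_av"),
               class = "murtree_error_fit_undefined")
  expect_error(fit_daily_linear(daily_obs(t = c(1, 2), ppr = c(1, 2)), "t_av"),
               class = "murtree_error_domain")
})

test_that("derive_adjustment inverts the line at the reference PPR", {
  fit <- structure(list(intercept = -33.26, slope = 10.6, n = 36,
                        p_slope = 0.001, r2 = 0.5, which = "t_av"),
                   class = "mur_linfit")
  adj <- derive_adjustment(fit, 183)
  expect_equal(round_report(adj$pivot_t), 20.4)

  fit2 <- structure(list(intercept = 0, slope = 1, n = 10, p_slope = 0.01,
                         r2 = 0.9, which = "t_av"), class = "mur_linfit")
  expect_equal(derive_adjustment(fit2, 50)$pivot_t, 50)

  fit0 <- structure(list(intercept = 5, slope = 0, n = 10, p_slope = 1,
                         r2 = 0, which = "t_av"), class = "mur_linfit")
  expect_error(derive_adjustment(fit0, 50),
               class = "murtree_error_pivot_undefined")
})

test_that("the published transfer equations evaluate as printed", {
  adj_tav <- adjustment_params(10.6, 20.4, 183, "t_av")
  outdoor_july <- make_edition(first_day = as.Date("2014-07-03"), n_days = 4)
  # at the pivot the adjustment vanishes
  expect_equal(adjust_ppr(183, 20.4, adj_tav, outdoor_july), 183.0)
  # one degree above the pivot adds b * PPR/183
  expect_equal(adjust_ppr(183, 21.4, adj_tav, outdoor_july), 193.6)
  adj_tmax <- adjustment_params(7.6, 25.6, 183, "t_max")
  expect_equal(adjust_ppr(183, 25.6, adj_tmax, outdoor_july), 183.0)
})

test_that("adjustment applies only to outdoor June-September events", {
  adj <- adjustment_params(7.6, 25.6, 183, "t_max")
  indoor <- make_edition(indoor = TRUE, first_day = as.Date("2014-07-03"))
  expect_equal(adjust_ppr(100, 35, adj, indoor), 100)
  straddling <- make_edition(first_day = as.Date("2014-05-31"), n_days = 2)
  expect_equal(adjust_ppr(100, 35, adj, straddling), 100)
  october <- make_edition(first_day = as.Date("2014-10-01"))
  expect_equal(adjust_ppr(100, 35, adj, october), 100)
  summer <- make_edition(first_day = as.Date("2014-06-01"), n_days = 2)
  expect_gt(adjust_ppr(100, 35, adj, summer), 100)
  expect_error(adjust_ppr(100, NA, adj, summer),
               class = "murtree_error_adjustment_impossible")
})

test_that("adjustment is proportional, monotone and floored at zero", {
  adj <- adjustment_params(7.6, 25.6, 183, "t_max")
  ev <- make_edition(first_day = as.Date("2014-07-03"), n_days = 4)
  t <- 28.6
  corr1 <- adjust_ppr(100, t, adj, ev) - 100
  corr2 <- adjust_ppr(200, t, adj, ev) - 200
  expect_equal(corr2, 2 * corr1, tolerance = 1e-12)
  temps <- seq(5, 35, by = 0.5)
  vals <- vapply(temps, function(x) adjust_ppr(60, x, adj, ev), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(adjust_ppr(60, -30, adj, ev), 0)  # floored
})

test_that("fit -> derive round trip reproduces slope and analytic pivot", {
  cfg <- synth_config(seed = 2, ref_noise_sd = 0, temp_slope = 10.6,
                      temp_pivot = 20.4, temp_which = "t_av")
  daily <- generate_reference_daily(cfg)
  fit <- fit_daily_linear(daily, "t_av")
  expect_equal(fit$slope, 10.6, tolerance = 1e-9)
  adj <- derive_adjustment(fit, cfg$reference_ppr)
  expect_equal(adj$pivot_t, 20.4, tolerance = 1e-9)
})

test_that("temperature association verdict follows the slope p-value", {
  obs <- daily_obs(t = 1:10, ppr = 3 * (1:10) + 2)
  expect_true(check_temperature_association(obs, "t_av")$associated)
  flat <- daily_obs(t = 1:10, ppr = rep(4, 10))
  v <- check_temperature_association(flat, "t_av")
  expect_false(v$associated)
  expect_equal(v$r2, 0)
})
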