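# Calibration measures and the validation harness.

test_that("r_squared is the squared Pearson correlation", {
  obs <- c(3, 9, 4, 7, 12, 5, 8, 10, 6, 11)
  expect_equal(r_squared(obs, obs), 1.0)
  expect_equal(r_squared(obs, 2 * obs + 7), 1.0)  # affine-blind by design
  set.seed(8)
  pred <- obs + rnorm(10, 0, 2)
  # brute-force covariance formula oracle
  cv <- sum((obs - mean(obs)) * (pred - mean(pred)))
  oracle <- cv^2 / (sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(r_squared(obs, pred), oracle, tolerance = 1e-12)
  expect_error(r_squared(obs, rep(5, 10)),
               class = "murtree_error_degenerate")
  expect_error(r_squared(1:2, 1:2), class = "murtree_error_domain")
})

test_that("Fisher-z interval behaves at the extremes", {
  obs <- as.numeric(1:20)
  ci <- r_squared_ci(obs, obs * 3 + 1)
  expect_equal(unname(ci), c(1, 1), ignore_attr = TRUE)
  set.seed(21)
  x <- rnorm(500); y <- rnorm(500)
  ci0 <- r_squared_ci(x, y)
  expect_equal(unname(ci0["low"]), 0)
  expect_lt(ci0["high"], 0.05)
  # bootstrap alternative is seeded and reproducible
  b1 <- r_squared_ci(x[1:50], y[1:50], method = "bootstrap", seed = 9)
  b2 <- r_squared_ci(x[1:50], y[1:50], method = "bootstrap", seed = 9)
  expect_identical(b1, b2)
})

test_that("deviation bands are inclusive and partition the events", {
  obs <- c(100, 100, 100, 0, 50)
  pred <- c(100, 125, 570, 3, 20)
  b <- deviation_bands(obs, pred)
  expect_true(b$table$within[1])
  expect_true(b$table$within[2])       # boundary 25% counts as within
  expect_false(b$table$within[3])
  expect_true(b$table$over50[3])       # overprediction factor 5.7
  expect_equal(b$table$ratio[3], 5.7)
  expect_true(b$table$undefined_ratio[4])
  expect_true(b$table$under50[5])
  # partition: banded + undefined = all
  expect_equal(b$n_events, nrow(b$table))
  expect_equal(sum(!b$table$undefined_ratio) + b$n_undefined, b$n_events)
  all_in <- deviation_bands(obs[1:3], obs[1:3])
  expect_equal(all_in$n_within, 3)
  # unlike r_squared, bands are not affine-invariant
  shifted <- deviation_bands(obs[1:3], obs[1:3] * 2)
  expect_equal(shifted$n_within, 0)
})

test_that("validate reproduces the training identity and never refits", {
  reg <- default_registry(seed = 31)
  agg <- aggregate_events(reg$events, reg$encounters)
  daily <- generate_reference_daily(synth_config(seed = 31))
  model <- fit_mur_model(agg, daily, seed = 2,
                         minsplit_range = 5:8, maxdepth_range = 8:9)
  before <- tree_to_json(model$ppr_tree)
  v <- validate(model, agg, "development", temperatures = reg$temperatures)
  # crude development R^2 equals 1 - rel_error of the selected tree
  expect_equal(v$ppr$crude$r2, model$ppr_tree$r2_train, tolerance = 1e-10)
  expect_equal(tree_to_json(model$ppr_tree), before)  # pure evaluation
  # report accounting
  for (rep in c(v$ppr, list(v$tthr))) {
    expect_equal(nrow(rep$table), nrow(agg))
    expect_equal(sum(rep$table$within) + sum(!rep$table$within &
                                               !rep$table$undefined_ratio) +
                   rep$n_undefined, nrow(agg))
  }
  expect_s3_class(glance(v), "tbl_df")
  expect_equal(nrow(glance(v)), length(v$ppr) + 1L)
})

test_that("a temporal draw from the same generator validates close to training", {
  cfg <- synth_config(seed = 33)
  reg <- generate_registry(cfg)
  agg <- aggregate_events(reg$events, reg$encounters)
  model <- fit_mur_model(agg, NULL, seed = 3,
                         minsplit_range = 5:10, maxdepth_range = 8:10)
  cfg2 <- synth_config(seed = 133)
  reg2 <- generate_registry(cfg2)
  agg2 <- aggregate_events(reg2$events, reg2$encounters)
  v2 <- validate(model, agg2, "temporal")
  expect_gt(v2$ppr$crude$r2, model$ppr_tree$r2_train - 0.1)

  # an external world with a different category-effect function degrades
  scrambled <- default_true_effects_scrambled()
  reg3 <- generate_registry(synth_config(seed = 233,
                                         true_effects = scrambled))
  agg3 <- aggregate_events(reg3$events, reg3$encounters)
  v3 <- validate(model, agg3, "external")
  expect_lt(v3$ppr$crude$r2, model$ppr_tree$r2_train - 0.2)
})

test_that("model bundles survive JSON persistence", {
  reg <- default_registry(seed = 37)
  agg <- aggregate_events(reg$events, reg$encounters)
  daily <- generate_reference_daily(synth_config(seed = 37))
  model <- fit_mur_model(agg, daily, seed = 2,
                         minsplit_range = 5:8, maxdepth_range = 8:9)
  path <- withr::local_tempfile(fileext = ".json")
  mur_save_model(model, path)
  back <- mur_load_model(path)
  p1 <- predict(model, agg, temperatures = reg$temperatures)
  p2 <- predict(back, agg, temperatures = reg$temperatures)
  expect_equal(p1, p2)
  expect_equal(back$adj_tmax$pivot_t, model$adj_tmax$pivot_t)
  expect_equal(back$tthr_temp_tmax$associated,
               model$tthr_temp_tmax$associated)
})
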