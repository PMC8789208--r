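# Outcome construction, categorization, imputation and EPV.

test_that("compute_ppr counts official-day encounters per 10,000 attendees", {
  # registry-scale arithmetic: 131,181 patients on 22,251,084 attendees
  ed <- make_edition(attendance = 22251084)
  enc <- make_encounters("ev_2010", rep(ed$first_day, 131181))
  expect_equal(round_report(compute_ppr(enc, ed)), 59.0)

  # empty encounter set
  expect_equal(compute_ppr(make_encounters("x", as.Date(character())), ed), 0)

  # encounters the day before an official day are excluded
  ed2 <- make_edition(attendance = 10000)
  enc2 <- make_encounters("ev_2010",
                          c(ed2$first_day - 1, ed2$first_day, ed2$first_day))
  expect_equal(compute_ppr(enc2, ed2), 2.0)

  # missing fields never drop a patient from the count
  enc3 <- make_encounters("ev_2010", rep(ed2$first_day, 3),
                          dismissal = NA, age = NA)
  expect_equal(compute_ppr(enc3, ed2), 3.0)

  expect_error(compute_ppr(enc2, make_edition(attendance = NA)),
               class = "murtree_error_outcome_undefined")
})

test_that("compute_tthr counts only ambulance transfers, missing = non-transfer", {
  ed <- make_edition(attendance = 22251084)
  enc <- make_encounters("ev_2010", rep(ed$first_day, 2748),
                         dismissal = "hospital_by_ambulance")
  expect_equal(round_report(compute_tthr(enc, ed)), 1.2)

  ed2 <- make_edition(attendance = 2569150)
  enc2 <- make_encounters("ev_2010", rep(ed2$first_day, 335),
                          dismissal = "hospital_by_ambulance")
  expect_equal(round_report(compute_tthr(enc2, ed2)), 1.3)

  ed3 <- make_edition(attendance = 10000)
  enc3 <- make_encounters("ev_2010", rep(ed3$first_day, 4),
                          dismissal = c("own_means", "back_to_event",
                                        "other", NA))
  expect_equal(compute_tthr(enc3, ed3), 0.0)
})

test_that("tthr never exceeds ppr and both scale as 1/attendance", {
  ed <- make_edition(attendance = 20000)
  days <- rep(ed$first_day, 10)
  enc <- make_encounters("ev_2010", days,
                         dismissal = c(rep("hospital_by_ambulance", 3),
                                       rep("back_to_event", 7)))
  ppr1 <- compute_ppr(enc, ed); tthr1 <- compute_tthr(enc, ed)
  expect_true(tthr1 >= 0 && tthr1 <= ppr1)
  ed2 <- make_edition(attendance = 40000)
  expect_equal(compute_ppr(enc, ed2), ppr1 / 2)
  expect_equal(compute_tthr(enc, ed2), tthr1 / 2)
})

test_that("attendance classes use right-open bins", {
  expect_equal(as.character(classify_attendance(12000)), "a10_20k")
  expect_equal(as.character(classify_attendance(37000)), "a30_100k")
  expect_equal(as.character(classify_attendance(9999)), "lt10k")
  expect_equal(as.character(classify_attendance(c(10000, 20000, 30000,
                                                  1e5, 1e6))),
               c("a10_20k", "a20_30k", "a30_100k", "a100k_1M", "gt1M"))
  expect_true(is.ordered(classify_attendance(500)))
  expect_error(classify_attendance(0), class = "murtree_error_domain")
})

test_that("age classes apply the mixed-family override first", {
  expect_equal(as.character(classify_age(28, 20, 25)), "mixed_family")
  expect_equal(as.character(classify_age(22, 17, 16)), "mixed_family")
  expect_equal(as.character(classify_age(25, 22, 10)), "young_adults")
  expect_equal(as.character(classify_age(12, 10, 4)), "children")
  expect_equal(as.character(classify_age(40, 33, 12)), "middle_adults")
  expect_error(classify_age(NA, NA, NA),
               class = "murtree_error_classification")
  # totality and mutual exclusivity over a grid of statistics
  grid <- expand.grid(med = c(10, 16, 25, 30, 31, 50),
                      q1 = c(10, 17, 20, 21, 30),
                      iqr = c(5, 15, 16, 20, 21, 40))
  cls <- classify_age(grid$med, grid$q1, grid$iqr)
  expect_false(anyNA(cls))
  mixed <- (grid$q1 < 21 & grid$iqr > 20) | (grid$q1 < 18 & grid$iqr > 15)
  expect_equal(as.character(cls) == "mixed_family", unname(mixed))
})

test_that("days classes bin 1 / 2 / 3-plus", {
  expect_equal(as.character(classify_days(c(1, 2, 4))),
               c("d1", "d2", "d3plus"))
  expect_equal(as.character(classify_days(list(as.Date("2010-01-01") + 0:2))),
               "d3plus")
})

test_that("attendance imputation applies only the two documented rules", {
  ser <- tibble::tibble(
    event_id = paste0("s_", 2010:2012), year = 2010:2012,
    attendance = c(20000, NA, 30000), sold_out = FALSE
  )
  out <- impute_attendance(ser)
  expect_equal(out$attendance, c(20000, 25000, 30000))
  expect_equal(out$attendance_source,
               c("observed", "interpolated", "observed"))

  sold <- tibble::tibble(
    event_id = paste0("s_", 2010:2013), year = 2010:2013,
    attendance = c(35000, NA, NA, NA), sold_out = TRUE
  )
  out2 <- impute_attendance(sold)
  expect_equal(out2$attendance, rep(35000, 4))
  expect_equal(out2$attendance_source[-1], rep("sold_out_copy", 3))

  # gap at the first edition matches neither rule
  first_gap <- tibble::tibble(
    event_id = paste0("s_", 2010:2011), year = 2010:2011,
    attendance = c(NA, 20000), sold_out = FALSE
  )
  expect_error(impute_attendance(first_gap),
               class = "murtree_error_unresolvable_missing")

  # observed values are never altered
  expect_equal(out$attendance[c(1, 3)], ser$attendance[c(1, 3)])
})

test_that("EPV is the event / candidate ratio to one decimal", {
  expect_equal(compute_epv(194, 9)$epv, 21.6)
  expect_equal(compute_epv(100, 10)$epv, 10.0)
  expect_equal(compute_epv(194, 12)$epv, 16.2)
  expect_error(compute_epv(100, 0), class = "murtree_error_domain")
})

test_that("aggregation builds consistent event-level outcomes and classes", {
  reg <- default_registry(seed = 3)
  agg <- aggregate_events(reg$events, reg$encounters)
  expect_equal(nrow(agg), nrow(reg$events))
  expect_true(all(agg$tthr <= agg$ppr + 1e-12))
  expect_true(all(agg$ppr >= 0))
  expect_equal(agg$ppr, 1e4 * agg$n_patients / agg$attendance)
  expect_equal(as.character(agg$days_class),
               as.character(classify_days(agg$n_days)))
  # included + excluded-by-date encounters partition the registry
  expect_equal(sum(agg$n_patients), nrow(reg$encounters))
  leak <- corrupt_for_robustness(reg, "date_leakage")
  agg2 <- aggregate_events(leak$events, leak$encounters)
  expect_equal(sum(agg2$n_patients), sum(agg$n_patients))
  expect_equal(nrow(leak$encounters) - sum(agg2$n_patients),
               2 * nrow(leak$manifest))
})
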