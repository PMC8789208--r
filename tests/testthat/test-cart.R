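# The regression-tree engine: split search, growth, prediction, surrogates,
# cross-validation, grid search, importance, serialization.

test_that("best_split finds the SSE-optimal partition", {
  d <- tibble::tibble(y = c(10, 10, 50, 50),
                      v = factor(c("A", "A", "B", "B")))
  s <- best_split(d, "v", outcome = "y")
  expect_equal(s$left_levels, "A")
  expect_equal(s$sse_reduction, 1600)
  expect_equal(c(s$n_left, s$n_right), c(2L, 2L))

  # constant outcome: nothing to gain
  d2 <- tibble::tibble(y = rep(7, 6), v = factor(rep(c("A", "B", "C"), 2)))
  expect_null(best_split(d2, "v", outcome = "y"))
})

test_that("engine split equals exhaustive enumeration on random fixtures", {
  for (seed in 1:40) {
    d <- random_fixture(n = 9, k_levels = 3, n_vars = 1, seed = seed)
    s <- best_split(d, "v1", outcome = "y")
    o <- oracle_best_reduction(d$y, d$v1)
    if (is.null(s)) {
      expect_true(is.null(o) || o$reduction <= 1e-9)
    } else {
      expect_equal(s$sse_reduction, o$reduction, tolerance = 1e-9)
    }
  }
})

test_that("exhaustive search agrees with the sort-by-node-mean shortcut", {
  for (seed in 41:80) {
    d <- random_fixture(n = 14, k_levels = 4, n_vars = 1, seed = seed)
    s <- best_split(d, "v1", outcome = "y")
    m <- sorted_mean_best_reduction(d$y, d$v1)
    if (!is.null(s)) expect_equal(s$sse_reduction, m, tolerance = 1e-9)
  }
})

test_that("ordered predictors only get order-respecting cuts", {
  d <- tibble::tibble(
    y = c(0, 100, 0, 100, 0, 100),
    v = factor(c("lo", "hi", "lo", "hi", "lo", "hi"),
               levels = c("lo", "mid", "hi"), ordered = TRUE)
  )
  s <- best_split(d, "v", outcome = "y")
  # cut assigns the absent middle level with the lower side of the cut
  expect_equal(s$left_levels, c("lo", "mid"))
  d2 <- tibble::tibble(
    y = c(10, 80, 10, 80, 10, 15),
    v = factor(c("a", "b", "a", "b", "a", "c"), ordered = TRUE)
  )
  s2 <- best_split(d2, "v", outcome = "y")
  o2 <- oracle_best_reduction(d2$y, d2$v, ordered = TRUE)
  expect_equal(s2$sse_reduction, o2$reduction, tolerance = 1e-9)
})

test_that("grow_tree separates a perfectly split outcome at depth 1", {
  d <- tibble::tibble(y = rep(c(5, 45), each = 6),
                      v = factor(rep(c("A", "B"), each = 6)))
  tr <- grow_tree(d, "y", "v", fit_config(minsplit = 2))
  expect_equal(tr$n_terminal, 2L)
  expect_equal(tr$rel_error, 0)
  expect_equal(tr$r2_train, 1)
  expect_equal(sort(names(tr$nodes)), sort(c("1", "2", "3")))
})

test_that("cp = 1 blocks all splits on noisy data", {
  d <- tree_fixture(noise = 2)
  tr <- grow_tree(d, "y", c("g1", "g2", "inert"),
                  fit_config(cp = 1, minsplit = 2))
  expect_equal(tr$n_terminal, 1L)
  expect_equal(predict(tr, d)$pred, rep(mean(d$y), nrow(d)))
  expect_equal(rel_error(tr, d), 1)
})

test_that("grown tree matches an independent greedy oracle on a 20-point fixture", {
  d <- random_fixture(n = 20, k_levels = 3, n_vars = 3, seed = 7)
  cfg <- fit_config(cp = 0.01, minsplit = 5, maxdepth = 8)
  tr <- grow_tree(d, "y", c("v1", "v2", "v3"), cfg)

  # independent recursive greedy: direct SSE sums, combn subsets
  oracle_leaf_means <- function(y, X, depth) {
    root_sse <- attr(X, "root_sse")
    if (length(y) < cfg$minsplit || depth >= cfg$maxdepth ||
        sum((y - mean(y))^2) == 0) {
      return(mean(y))
    }
    best <- NULL
    for (v in names(X)) {
      o <- oracle_best_reduction(y, X[[v]])
      if (!is.null(o) && (is.null(best) ||
                          o$reduction > best$red + 1e-9)) {
        best <- list(red = o$reduction, left = o$left, var = v)
      }
    }
    if (is.null(best) || best$red < cfg$cp * root_sse) return(mean(y))
    go <- as.character(X[[best$var]]) %in% best$left
    Xl <- lapply(X, `[`, go); Xr <- lapply(X, `[`, !go)
    attr(Xl, "root_sse") <- root_sse; attr(Xr, "root_sse") <- root_sse
    c(oracle_leaf_means(y[go], Xl, depth + 1),
      oracle_leaf_means(y[!go], Xr, depth + 1))
  }
  X <- list(v1 = d$v1, v2 = d$v2, v3 = d$v3)
  attr(X, "root_sse") <- sum((d$y - mean(d$y))^2)
  oracle_means <- oracle_leaf_means(d$y, X, 0)
  leaf_means <- vapply(Filter(function(nd) is.null(nd$split), tr$nodes),
                       `[[`, numeric(1), "mean")
  expect_equal(sort(unname(leaf_means)), sort(oracle_means),
               tolerance = 1e-9)
})

test_that("node bookkeeping invariants hold on a fitted tree", {
  reg <- default_registry(seed = 11)
  agg <- aggregate_events(reg$events, reg$encounters)
  tr <- grow_tree(agg, "ppr", config = fit_config(minsplit = 10,
                                                  maxdepth = 6))
  ids <- as.integer(names(tr$nodes))
  for (id in ids[ids > 1]) {
    expect_true(id %/% 2 %in% ids)  # heap numbering
  }
  for (nd in tr$nodes) {
    if (!is.null(nd$split)) {
      kids <- tr$nodes[as.character(c(2 * nd$id, 2 * nd$id + 1))]
      expect_equal(kids[[1]]$n + kids[[2]]$n, nd$n)
      expect_lte(kids[[1]]$sse + kids[[2]]$sse, nd$sse + 1e-9)
    }
  }
  # leaf predictions are exact means: residuals sum to zero per leaf
  pred <- predict(tr, agg)
  res <- agg$ppr - pred$pred
  sums <- tapply(res, pred$node_id, sum)
  expect_true(all(abs(sums) < 1e-8))
  # training 1 - rel_error equals the squared correlation identity
  expect_equal(1 - rel_error(tr, agg), cor(agg$ppr, pred$pred)^2,
               tolerance = 1e-12)
})

test_that("prediction routes training rows to their own leaves and handles unseen levels", {
  d <- tree_fixture(noise = 1)
  tr <- grow_tree(d, "y", c("g1", "g2", "inert"), fit_config(minsplit = 2))
  pred <- predict(tr, d)
  for (leaf in unique(pred$node_id)) {
    expect_equal(unique(pred$pred[pred$node_id == leaf]),
                 mean(d$y[pred$node_id == leaf]))
  }
  # masking the primary split variable: a perfectly correlated surrogate
  # must route to the same leaf
  d2 <- tibble::tibble(
    y = rep(c(5, 45), each = 10),
    main = factor(rep(c("A", "B"), each = 10)),
    shadow = factor(rep(c("u", "v"), each = 10))
  )
  tr2 <- grow_tree(d2, "y", c("main", "shadow"), fit_config(minsplit = 2))
  expect_gte(length(tr2$nodes[["1"]]$surrogates), 1)
  expect_equal(tr2$nodes[["1"]]$surrogates[[1]]$agreement, 1.0)
  masked <- d2; masked$main <- factor(NA, levels = levels(d2$main))
  expect_equal(predict(tr2, masked)$node_id, predict(tr2, d2)$node_id)
})

test_that("variable importance is normalized and credits surrogates", {
  d <- tibble::tibble(
    y = rep(c(5, 45), each = 10),
    main = factor(rep(c("A", "B"), each = 10)),
    shadow = factor(rep(c("u", "v"), each = 10))
  )
  tr <- grow_tree(d, "y", c("main", "shadow"), fit_config(minsplit = 2))
  vi <- variable_importance(tr)
  expect_equal(sum(vi$importance), 100, tolerance = 1e-9)
  expect_setequal(vi$variable, c("main", "shadow"))
  expect_true(all(vi$importance > 0))

  d_single <- tibble::tibble(y = rep(c(1, 9), each = 5),
                             v = factor(rep(c("A", "B"), each = 5)))
  tr_single <- grow_tree(d_single, "y", "v", fit_config(minsplit = 2))
  vi_single <- variable_importance(tr_single)
  expect_equal(vi_single$importance, 100)

  d_noisy <- tibble::tibble(y = c(1, 9, 5, 6), v = factor(c("A", "B", "A", "B")))
  root_only <- grow_tree(d_noisy, "y", "v", fit_config(cp = 1, minsplit = 2))
  expect_equal(root_only$n_terminal, 1L)
  expect_equal(nrow(variable_importance(root_only)), 0)
})

test_that("cross-validation is seed-deterministic and calibrated to signal", {
  d <- tree_fixture(n_per = 12, noise = 2)
  cfg <- fit_config(minsplit = 5, n_folds = 10, seed = 3)
  cv1 <- cross_validate(d, "y", c("g1", "g2", "inert"), cfg)
  cv2 <- cross_validate(d, "y", c("g1", "g2", "inert"), cfg)
  expect_identical(cv1$xerror, cv2$xerror)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  tab <- table(cv1$fold_assignment)
  expect_lte(max(tab) - min(tab), 1)  # balanced folds
  expect_lt(cv1$xerror, 1)            # strong signal predicts better than mean

  # pure noise: held-out error near or above the root error
  set.seed(42)
  xs <- replicate(60, {
    dn <- tibble::tibble(y = rnorm(40),
                         v1 = factor(sample(letters[1:3], 40, TRUE)),
                         v2 = factor(sample(letters[1:4], 40, TRUE)))
    cross_validate(dn, "y", c("v1", "v2"),
                   fit_config(minsplit = 5, seed = 1))$xerror
  })
  expect_gt(mean(xs), 0.95)
})

test_that("grid search enumerates the full grid and returns the xerror argmin", {
  reg <- default_registry(seed = 13)
  agg <- aggregate_events(reg$events, reg$encounters)
  tr <- grid_search(agg, "ppr", seed = 5)
  expect_equal(nrow(tr$grid), 128L)
  expect_equal(nrow(dplyr::distinct(tr$grid[, c("minsplit", "maxdepth")])),
               128L)
  expect_lte(tr$xerror, min(tr$grid$xerror) + 1e-12)

  # degenerate 1x1 grid
  tr1 <- grid_search(agg, "ppr", minsplit_range = 5, maxdepth_range = 8,
                     seed = 5)
  expect_equal(nrow(tr1$grid), 1L)

  # the pruned-maximal-tree shortcut must match direct per-config CV
  for (row in c(1, 40, 128)) {
    cfg <- fit_config(minsplit = tr$grid$minsplit[row],
                      maxdepth = tr$grid$maxdepth[row], seed = 5)
    cv <- cross_validate(agg, "ppr", config = cfg)
    expect_equal(tr$grid$xerror[row], cv$xerror, tolerance = 1e-10)
  }
})

test_that("fitted trees agree with rpart on a well-separated fixture", {
  skip_if_not_installed("rpart")
  reg <- default_registry(seed = 17)
  agg <- aggregate_events(reg$events, reg$encounters)
  cfg <- fit_config(cp = 0.01, minsplit = 10, maxdepth = 8)
  tr <- grow_tree(agg, "ppr", config = cfg)
  agg_rp <- dplyr::mutate(agg, dplyr::across(c("indoor", "bounded",
                                               "camping"), ~ factor(.x)))
  rp <- rpart::rpart(
    ppr ~ category + attendance_class + age_class + days_class + timing +
      indoor + bounded + camping + alcohol,
    data = agg_rp, method = "anova",
    control = rpart::rpart.control(cp = 0.01, minsplit = 10, minbucket = 1,
                                   maxdepth = 8, xval = 0))
  expect_equal(sort(unique(predict(tr, agg)$pred)),
               sort(unique(unname(predict(rp, agg_rp)))),
               tolerance = 1e-8)
})

test_that("serialization round-trips structure and predictions", {
  reg <- default_registry(seed = 19)
  agg <- aggregate_events(reg$events, reg$encounters)
  tr <- grow_tree(agg, "ppr", config = fit_config(minsplit = 10))
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tr, path)
  back <- tree_from_json(path)
  expect_equal(predict(back, agg), predict(tr, agg))
  expect_equal(back$rel_error, tr$rel_error)
  expect_equal(back$n_terminal, tr$n_terminal)
  expect_equal(tidy(back)$split_variable, tidy(tr)$split_variable)
})

test_that("tidy and glance expose the fitted tree as tibbles", {
  d <- tree_fixture(noise = 1)
  tr <- grow_tree(d, "y", c("g1", "g2", "inert"), fit_config(minsplit = 2))
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$terminal), tr$n_terminal)
  gl <- glance(tr)
  expect_equal(gl$n, nrow(d))
  expect_equal(gl$r2_train, 1 - gl$rel_error)
})
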