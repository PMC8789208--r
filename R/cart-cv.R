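# 10-fold cross-validation and the hyperparameter grid search.
#
# Key observation used by the grid search: the split chosen at a node does
# not depend on minsplit or maxdepth — those only gate whether a split is
# attempted — and the cp gate is relative to the root SSE, which is also
# config-independent. The tree at any (minsplit, maxdepth) is therefore a
# pruned subtree of the maximal tree grown at (min(minsplit), max(maxdepth)),
# keeping a split iff its node has n >= minsplit and depth < maxdepth
# (gate-passing is upward-closed along any root-to-leaf path). The grid is
# evaluated by growing one maximal tree per fold and re-reading held-out
# predictions at each gate, instead of regrowing 128 x n_folds trees.

assign_folds <- function(n, n_folds, seed) {
  with_preserved_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
}

fold_tree <- function(design, config, idx) {
  grown <- grow_nodes(design, config, idx)
  structure(list(nodes = grown$nodes,
                 predictors = purrr::map(design$vars,
                                         ~ list(levels = .x$levels,
                                                ordered = .x$ordered))),
            class = "mur_tree")
}

# Per-observation root-to-leaf paths through a tree, as padded matrices of
# node means / sizes / depths / leaf flags (padding repeats the leaf).
path_matrices <- function(tree, newdata) {
  vals <- values_matrix(tree, newdata)
  n <- nrow(newdata)
  paths <- purrr::map(seq_len(n), function(i) {
    route_one(tree, lapply(vals, `[[`, i))
  })
  maxlen <- max(lengths(paths))
  mean_m <- matrix(NA_real_, n, maxlen)
  n_m <- matrix(0L, n, maxlen)
  depth_m <- matrix(0L, n, maxlen)
  leaf_m <- matrix(TRUE, n, maxlen)
  for (i in seq_len(n)) {
    p <- paths[[i]]
    for (j in seq_along(p)) {
      nd <- tree$nodes[[as.character(p[j])]]
      mean_m[i, j] <- nd$mean
      n_m[i, j] <- nd$n
      depth_m[i, j] <- nd$depth
      leaf_m[i, j] <- is.null(nd$split)
    }
    if (length(p) < maxlen) {
      pad <- (length(p) + 1):maxlen
      mean_m[i, pad] <- mean_m[i, length(p)]
      n_m[i, pad] <- 0L
      depth_m[i, pad] <- depth_m[i, length(p)]
      leaf_m[i, pad] <- TRUE
    }
  }
  list(mean = mean_m, n = n_m, depth = depth_m, leaf = leaf_m)
}

# Held-out prediction for a given (minsplit, maxdepth): the mean at the
# first node along each path that would be terminal under the gates.
prune_predict <- function(pm, minsplit, maxdepth) {
  fail <- pm$leaf | pm$n < minsplit | pm$depth >= maxdepth
  first <- max.col(fail, ties.method = "first")
  pm$mean[cbind(seq_len(nrow(fail)), first)]
}

#' Cross-validated relative error of a tree configuration
#'
#' Assigns observations to balanced folds by a seeded permutation, grows a
#' tree on each training fold with the same configuration, and accumulates
#' held-out squared errors. `xerror` is the held-out SSE divided by the SSE
#' of the root (grand mean) on the full data; values near or above 1 mean
#' the tree predicts no better than the overall mean.
#'
#' @inheritParams grow_tree
#' @return A `mur_cv` list: `xerror`, `xstd` (approximate standard error),
#'   `fold_assignment`.
#' @export
cross_validate <- function(data, outcome = "ppr",
                           predictors = mur_base_predictors,
                           config = fit_config()) {
  design <- make_design(data, outcome, predictors)
  n <- design$n
  if (n < config$n_folds) {
    mur_stop("Fewer observations than folds.", class = "murtree_error_domain")
  }
  folds <- assign_folds(n, config$n_folds, config$seed)
  y <- design$y
  sse0 <- sum((y - mean(y))^2)
  if (sse0 == 0) {
    mur_stop("Outcome has zero variance: xerror undefined.",
             class = "murtree_error_degenerate")
  }
  err2 <- numeric(n)
  for (f in seq_len(config$n_folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    tr <- fold_tree(design, config, train)
    pred <- predict(tr, data[test, , drop = FALSE])$pred
    err2[test] <- (y[test] - pred)^2
  }
  structure(list(
    xerror = sum(err2) / sse0,
    xstd = stats::sd(err2) * sqrt(n) / sse0,
    fold_assignment = folds
  ), class = "mur_cv")
}

#' Hyperparameter grid search with minimal-xerror selection
#'
#' Evaluates every (minsplit, maxdepth) combination — 16 x 8 = 128 models
#' with the default ranges — by 10-fold cross-validation at a fixed
#' complexity parameter, and returns the tree with minimal cross-validated
#' error. Fold assignment is shared across the whole grid so models are
#' compared on identical splits. Ties in xerror are broken towards fewer
#' terminal nodes, then smaller minsplit, then smaller maxdepth.
#'
#' @inheritParams grow_tree
#' @param minsplit_range,maxdepth_range Integer vectors of values to combine.
#' @param cp Complexity parameter shared by all grid points.
#' @param minbucket Minimum child size.
#' @param n_folds Number of CV folds.
#' @param seed Fold-assignment seed.
#' @return The selected `mur_tree`, with `xerror`/`xstd` filled in and the
#'   full grid report (one row per combination) in `$grid`.
#' @export
grid_search <- function(data, outcome = "ppr",
                        predictors = mur_base_predictors,
                        minsplit_range = 5:20, maxdepth_range = 8:15,
                        cp = 0.01, minbucket = 1L, n_folds = 10L, seed = 1L) {
  if (length(minsplit_range) == 0 || length(maxdepth_range) == 0) {
    mur_stop("Empty hyperparameter range.", class = "murtree_error_domain")
  }
  design <- make_design(data, outcome, predictors)
  n <- design$n
  if (n < n_folds) {
    mur_stop("Fewer observations than folds.", class = "murtree_error_domain")
  }
  y <- design$y
  sse0 <- sum((y - mean(y))^2)
  if (sse0 == 0) {
    mur_stop("Outcome has zero variance: xerror undefined.",
             class = "murtree_error_degenerate")
  }
  max_config <- fit_config(cp = cp, minsplit = min(minsplit_range),
                           maxdepth = max(maxdepth_range),
                           minbucket = minbucket, n_folds = n_folds,
                           seed = seed)
  folds <- assign_folds(n, n_folds, seed)

  # held-out paths through each fold's maximal tree
  fold_pms <- vector("list", n_folds)
  test_idx <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- which(folds == f)
    tr <- fold_tree(design, max_config, which(folds != f))
    fold_pms[[f]] <- path_matrices(tr, data[test, , drop = FALSE])
    test_idx[[f]] <- test
  }

  # full-data maximal tree (for terminal-node counts and the final fit)
  full_max <- grow_nodes(design, max_config)
  split_nodes <- purrr::keep(full_max$nodes, ~ !is.null(.x$split))
  split_n <- vapply(split_nodes, `[[`, numeric(1), "n")
  split_depth <- vapply(split_nodes, `[[`, numeric(1), "depth")

  grid <- tidyr::expand_grid(minsplit = as.integer(minsplit_range),
                             maxdepth = as.integer(maxdepth_range))
  res <- purrr::map(seq_len(nrow(grid)), function(g) {
    m <- grid$minsplit[g]; d <- grid$maxdepth[g]
    err2 <- numeric(n)
    for (f in seq_len(n_folds)) {
      pred <- prune_predict(fold_pms[[f]], m, d)
      err2[test_idx[[f]]] <- (y[test_idx[[f]]] - pred)^2
    }
    n_kept <- sum(split_n >= m & split_depth < d)
    tibble(xerror = sum(err2) / sse0,
           xstd = stats::sd(err2) * sqrt(n) / sse0,
           n_terminal = n_kept + 1L)
  })
  grid <- bind_cols(grid, bind_rows(res))

  tol <- 1e-9 * max(1, min(grid$xerror))
  best <- grid |>
    filter(.data$xerror <= min(.data$xerror) + tol) |>
    arrange(.data$n_terminal, .data$minsplit, .data$maxdepth) |>
    slice(1)
  sel_config <- fit_config(cp = cp, minsplit = best$minsplit,
                           maxdepth = best$maxdepth, minbucket = minbucket,
                           n_folds = n_folds, seed = seed)
  tree <- grow_tree(data, outcome, predictors, sel_config)
  tree$xerror <- best$xerror
  tree$xstd <- best$xstd
  tree$grid <- grid
  tree$fold_assignment <- folds
  tree
}
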