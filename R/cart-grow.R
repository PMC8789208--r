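# Recursive growth of the regression tree, prediction/routing, training
# error and variable importance.

#' Tree-fitting configuration
#'
#' @param cp Complexity parameter: a split is kept only if it decreases the
#'   overall lack of fit (root SSE) by at least this proportion. Default 0.01.
#' @param minsplit Minimum number of observations in a node for a split to
#'   be attempted. Default 5 (the lower end of the tuning grid).
#' @param maxdepth Maximum depth of any node (root has depth 0). Default 15
#'   (the upper end of the tuning grid).
#' @param minbucket Minimum number of observations in a child node. Default 1.
#' @param n_folds Number of cross-validation folds. Default 10.
#' @param seed Seed for the fold assignment permutation.
#' @return A `mur_config` list.
#' @export
fit_config <- function(cp = 0.01, minsplit = 5L, maxdepth = 15L,
                       minbucket = 1L, n_folds = 10L, seed = 1L) {
  stopifnot(cp >= 0, cp <= 1, minsplit >= 2, maxdepth >= 1,
            minbucket >= 1, n_folds >= 2)
  structure(list(cp = cp, minsplit = as.integer(minsplit),
                 maxdepth = as.integer(maxdepth),
                 minbucket = as.integer(minbucket),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "mur_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

grow_nodes <- function(design, config, idx = seq_len(design$n)) {
  y <- design$y
  root_sse <- sum((y[idx] - mean(y[idx]))^2)
  nodes <- list()
  build <- function(idx, depth, id) {
    yk <- y[idx]
    n <- length(idx)
    m <- mean(yk)
    sse <- sum((yk - m)^2)
    node <- list(id = id, depth = depth, n = n, mean = m,
                 sd = if (n > 1) sd(yk) else 0, sse = sse,
                 split = NULL, surrogates = list())
    if (n >= config$minsplit && depth < config$maxdepth && sse > 0) {
      cand <- NULL
      for (v in names(design$vars)) {
        var <- design$vars[[v]]
        s <- best_split_for_var(y, var$codes, var$levels, var$ordered, idx,
                                min_side = config$minbucket)
        if (is.null(s)) next
        s$variable <- v
        # strictly-better keeps the earliest declared variable on ties
        if (is.null(cand) ||
            s$sse_reduction > cand$sse_reduction +
              1e-9 * max(1, abs(cand$sse_reduction))) {
          cand <- s
        }
      }
      if (!is.null(cand) && cand$sse_reduction >= config$cp * root_sse) {
        var <- design$vars[[cand$variable]]
        goes_left <- var$levels[var$codes[idx]] %in% cand$left_levels
        node$split <- cand
        node$surrogates <- find_surrogates(design, idx, cand$variable,
                                           goes_left)
        nodes[[as.character(id)]] <<- node
        build(idx[goes_left], depth + 1, 2L * id)
        build(idx[!goes_left], depth + 1, 2L * id + 1L)
        return(invisible(NULL))
      }
    }
    nodes[[as.character(id)]] <<- node
    invisible(NULL)
  }
  build(idx, 0L, 1L)
  list(nodes = nodes, root_sse = root_sse)
}

#' Grow a regression tree
#'
#' Recursive binary partitioning of a continuous outcome over categorical
#' predictors. At each node the most discriminating predictor is chosen by
#' exhaustive search over binary level partitions; a split is kept only if
#' its SSE reduction is at least `cp` times the root SSE, the node holds at
#' least `minsplit` observations and its depth is below `maxdepth`. Node
#' predictions are training means; node ids follow heap numbering (root 1,
#' children of k are 2k and 2k + 1). Surrogate splits mimicking each primary
#' split are recorded for routing observations with unseen or missing
#' predictor levels.
#'
#' @param data Data frame of events (one row per edition).
#' @param outcome Name of the numeric outcome column.
#' @param predictors Character vector of categorical predictor columns, in
#'   declared order (earlier variables win ties).
#' @param config A [fit_config()] list.
#' @return A `mur_tree` object.
#' @export
grow_tree <- function(data, outcome = "ppr",
                      predictors = mur_base_predictors,
                      config = fit_config()) {
  design <- make_design(data, outcome, predictors)
  grown <- grow_nodes(design, config)
  new_mur_tree(grown$nodes, design, config, outcome, grown$root_sse)
}

new_mur_tree <- function(nodes, design, config, outcome, root_sse) {
  leaf_sse <- sum(vapply(nodes, function(nd)
    if (is.null(nd$split)) nd$sse else 0, numeric(1)))
  rel_err <- if (root_sse > 0) leaf_sse / root_sse else NA_real_
  structure(list(
    nodes = nodes,
    config = config,
    outcome = outcome,
    predictors = purrr::map(design$vars,
                            ~ list(levels = .x$levels, ordered = .x$ordered)),
    n = design$n,
    root_sse = root_sse,
    rel_error = rel_err,
    r2_train = if (is.na(rel_err)) NA_real_ else 1 - rel_err,
    n_terminal = sum(vapply(nodes, function(nd) is.null(nd$split), logical(1))),
    xerror = NA_real_,
    xstd = NA_real_
  ), class = "mur_tree")
}

# Route one observation (named character vector of predictor levels, NA
# allowed) through the tree; returns the vector of visited node ids.
route_one <- function(tree, values) {
  path <- integer(0)
  id <- 1L
  repeat {
    node <- tree$nodes[[as.character(id)]]
    path <- c(path, id)
    if (is.null(node$split)) return(path)
    apply_split <- function(sp) {
      val <- values[[sp$variable]]
      if (is.null(val) || is.na(val)) return(NA)
      if (val %in% sp$left_levels) return(TRUE)
      if (val %in% sp$right_levels) return(FALSE)
      NA
    }
    primary_val <- values[[node$split$variable]]
    dir <- apply_split(node$split)
    if (is.na(dir)) {
      for (sur in node$surrogates) {
        dir <- apply_split(sur)
        if (!is.na(dir)) break
      }
    }
    if (is.na(dir)) {
      if (node$split$n_left > node$split$n_right) dir <- TRUE
      else if (node$split$n_right > node$split$n_left) dir <- FALSE
      else if (!is.null(primary_val) && !is.na(primary_val)) {
        # observed but unseen level with tied children: deterministic left
        dir <- TRUE
      } else mur_stop(
        sprintf("Cannot route at node %d: split variable '%s' missing, no applicable surrogate and no majority direction.",
                id, node$split$variable),
        class = "murtree_error_routing")
    }
    id <- if (dir) 2L * id else 2L * id + 1L
  }
}

values_matrix <- function(tree, newdata) {
  vars <- names(tree$predictors)
  vals <- lapply(vars, function(v) {
    col <- newdata[[v]]
    if (is.null(col)) return(rep(NA_character_, nrow(newdata)))
    if (is.logical(col)) ifelse(col, "true", "false") else as.character(col)
  })
  names(vals) <- vars
  vals
}

#' Predict from a fitted regression tree
#'
#' Routes each event through the tree's splits and returns the terminal
#' node's training mean. A level unseen at a split (or a missing split
#' variable) is routed by the first applicable surrogate split, else by the
#' majority direction of the training data.
#'
#' @param object A `mur_tree`.
#' @param newdata Data frame with the predictor columns used by the tree.
#' @param ... Unused.
#' @return Tibble with one row per input row: `node_id` (terminal node) and
#'   `pred` (that node's mean outcome).
#' @export
predict.mur_tree <- function(object, newdata, ...) {
  vals <- values_matrix(object, newdata)
  vars <- names(vals)
  out <- purrr::map(seq_len(nrow(newdata)), function(i) {
    obs <- lapply(vals, `[[`, i)
    path <- route_one(object, obs)
    leaf <- path[length(path)]
    tibble(node_id = leaf, pred = object$nodes[[as.character(leaf)]]$mean)
  })
  bind_rows(out)
}

#' Training relative error and R-squared of a tree
#'
#' `rel_error()` is the tree's SSE divided by the root SSE on the data;
#' `r_squared_train()` is one minus that, which on training data equals the
#' squared Pearson correlation between observed outcomes and leaf-mean
#' predictions.
#'
#' @param tree A `mur_tree`.
#' @param data Data frame to evaluate on (the training data for the
#'   identities above to hold).
#' @return A single ratio.
#' @export
rel_error <- function(tree, data) {
  y <- data[[tree$outcome]]
  sse0 <- sum((y - mean(y))^2)
  if (sse0 == 0) {
    mur_stop("Outcome has zero variance: relative error undefined.",
             class = "murtree_error_degenerate")
  }
  pred <- predict(tree, data)$pred
  sum((y - pred)^2) / sse0
}

#' @rdname rel_error
#' @export
r_squared_train <- function(tree, data) {
  1 - rel_error(tree, data)
}

#' Variable importance
#'
#' Credit for each predictor's ability to perform in the tree, either as a
#' primary splitter (its splits' SSE reductions) or as a surrogate splitter
#' (the primary split's SSE reduction weighted by the surrogate's
#' agreement). Scores are normalized to percentages summing to 100.
#'
#' @param tree A fitted `mur_tree`.
#' @return Tibble with `variable` and `importance` (percent), sorted
#'   decreasing; zero rows for a root-only tree.
#' @export
variable_importance <- function(tree) {
  raw <- setNames(numeric(length(tree$predictors)), names(tree$predictors))
  for (node in tree$nodes) {
    if (is.null(node$split)) next
    red <- node$split$sse_reduction
    raw[node$split$variable] <- raw[node$split$variable] + red
    for (sur in node$surrogates) {
      raw[sur$variable] <- raw[sur$variable] + sur$agreement * red
    }
  }
  raw <- raw[raw > 0]
  if (length(raw) == 0) {
    return(tibble(variable = character(0), importance = numeric(0)))
  }
  tibble(variable = names(raw), importance = unname(100 * raw / sum(raw))) |>
    arrange(desc(.data$importance))
}

#' @export
print.mur_tree <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.mur_tree <- function(x, ...) {
  lines <- c(sprintf(
    "Regression tree for '%s': %d observations, %d terminal nodes, rel error %.3f",
    x$outcome, x$n, x$n_terminal,
    if (is.na(x$rel_error)) NaN else x$rel_error))
  render <- function(id, indent) {
    node <- x$nodes[[as.character(id)]]
    pad <- strrep("  ", indent)
    if (is.null(node$split)) {
      lines <<- c(lines, sprintf("%s[%d] leaf: %.1f +/- %.1f (n = %d)",
                                 pad, id, node$mean, node$sd, node$n))
    } else {
      lines <<- c(lines, sprintf(
        "%s[%d] %s in {%s} (n = %d, mean %.1f)", pad, id,
        node$split$variable, paste(node$split$left_levels, collapse = ", "),
        node$n, node$mean))
      render(2L * id, indent + 1)
      render(2L * id + 1L, indent + 1)
    }
  }
  render(1L, 1)
  lines
}

#' Tidy a fitted regression tree
#'
#' @param x A `mur_tree`.
#' @param ... Unused.
#' @return Tibble with one row per node: id, depth, size, mean, sd, split
#'   variable (NA for leaves), left level set and SSE reduction.
#' @method tidy mur_tree
#' @export
tidy.mur_tree <- function(x, ...) {
  rows <- purrr::map(x$nodes, function(nd) {
    tibble(
      node_id = nd$id, depth = nd$depth, n = nd$n,
      mean = nd$mean, sd = nd$sd, terminal = is.null(nd$split),
      split_variable = if (is.null(nd$split)) NA_character_
                       else nd$split$variable,
      left_levels = if (is.null(nd$split)) NA_character_
                    else paste(nd$split$left_levels, collapse = ","),
      sse_reduction = if (is.null(nd$split)) NA_real_
                      else nd$split$sse_reduction,
      n_surrogates = length(nd$surrogates)
    )
  })
  bind_rows(rows) |> arrange(.data$node_id)
}

#' Glance at a fitted regression tree
#'
#' @param x A `mur_tree`.
#' @param ... Unused.
#' @return One-row tibble: n, number of terminal nodes, rel error, training
#'   R-squared, cross-validated error (NA unless set by [cross_validate()]
#'   or [grid_search()]), and the configuration.
#' @method glance mur_tree
#' @export
glance.mur_tree <- function(x, ...) {
  tibble(n = x$n, n_terminal = x$n_terminal, rel_error = x$rel_error,
         r2_train = x$r2_train, xerror = x$xerror, xstd = x$xstd,
         cp = x$config$cp, minsplit = x$config$minsplit,
         maxdepth = x$config$maxdepth)
}
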