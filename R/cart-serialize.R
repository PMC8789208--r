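# Plain-text (JSON) persistence of fitted trees, so a model developed once
# can be reapplied to validation datasets without refitting.

split_to_list <- function(sp) {
  if (is.null(sp)) return(NULL)
  list(variable = sp$variable,
       left_levels = as.list(sp$left_levels),
       right_levels = as.list(sp$right_levels),
       sse_reduction = sp$sse_reduction,
       n_left = sp$n_left, n_right = sp$n_right,
       agreement = sp$agreement)
}

split_from_list <- function(sp) {
  if (is.null(sp)) return(NULL)
  out <- list(variable = sp$variable,
              left_levels = unlist(sp$left_levels),
              right_levels = unlist(sp$right_levels))
  if (!is.null(sp$sse_reduction)) out$sse_reduction <- sp$sse_reduction
  if (!is.null(sp$n_left)) out$n_left <- as.integer(sp$n_left)
  if (!is.null(sp$n_right)) out$n_right <- as.integer(sp$n_right)
  if (!is.null(sp$agreement)) out$agreement <- sp$agreement
  out
}

#' Serialize a fitted tree to JSON text
#'
#' Writes every node (splits, surrogate splits, means, sizes), the fit
#' configuration, predictor level sets and fit diagnostics to a documented
#' JSON structure, so the exact model can be reloaded and applied to new
#' datasets. [tree_from_json()] restores the `mur_tree`.
#'
#' @param tree A `mur_tree`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(
    format = "murtree/1",
    outcome = tree$outcome,
    n = tree$n,
    root_sse = tree$root_sse,
    rel_error = tree$rel_error,
    r2_train = tree$r2_train,
    n_terminal = tree$n_terminal,
    xerror = tree$xerror,
    xstd = tree$xstd,
    config = unclass(tree$config),
    predictors = purrr::map(tree$predictors, function(p) {
      list(levels = as.list(p$levels), ordered = p$ordered)
    }),
    nodes = purrr::map(unname(tree$nodes), function(nd) {
      list(id = nd$id, depth = nd$depth, n = nd$n, mean = nd$mean,
           sd = nd$sd, sse = nd$sse,
           split = split_to_list(nd$split),
           surrogates = purrr::map(nd$surrogates, split_to_list))
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname tree_to_json
#' @param json A path to a JSON file written by [tree_to_json()], or the
#'   JSON text itself.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(obj$format, "murtree/1")) {
    mur_stop("Not a serialized murtree model.", class = "murtree_error_schema")
  }
  nodes <- purrr::map(obj$nodes, function(nd) {
    list(id = as.integer(nd$id), depth = as.integer(nd$depth),
         n = as.integer(nd$n), mean = nd$mean, sd = nd$sd, sse = nd$sse,
         split = split_from_list(nd$split),
         surrogates = purrr::map(nd$surrogates, split_from_list))
  })
  names(nodes) <- vapply(nodes, function(nd) as.character(nd$id), character(1))
  cfg <- obj$config
  config <- fit_config(cp = cfg$cp, minsplit = cfg$minsplit,
                       maxdepth = cfg$maxdepth, minbucket = cfg$minbucket,
                       n_folds = cfg$n_folds, seed = cfg$seed)
  structure(list(
    nodes = nodes,
    config = config,
    outcome = obj$outcome,
    predictors = purrr::map(obj$predictors, function(p) {
      list(levels = unlist(p$levels), ordered = isTRUE(p$ordered))
    }),
    n = as.integer(obj$n),
    root_sse = obj$root_sse,
    rel_error = obj$rel_error %||% NA_real_,
    r2_train = obj$r2_train %||% NA_real_,
    n_terminal = as.integer(obj$n_terminal),
    xerror = obj$xerror %||% NA_real_,
    xstd = obj$xstd %||% NA_real_
  ), class = "mur_tree")
}
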