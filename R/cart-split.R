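# Split search for the regression-tree engine. Outcomes are continuous;
# predictors are categorical (nominal or ordered). The best split of a node
# is the binary partition of one predictor's levels that maximizes the
# reduction in the sum of squared errors,
#   reduction = SSE(parent) - SSE(left) - SSE(right)
#             = sL^2/nL + sR^2/nR - S^2/N          (between-group SS),
# where s are outcome sums within the partition sides.

# Convert a modelling frame into the engine's internal design: outcome
# vector + per-predictor integer codes, level labels and orderedness.
# Logical predictors become two-level factors ("false" < "true" order only
# in the sense of level listing; they are treated as nominal, which for two
# levels is equivalent).
make_design <- function(data, outcome, predictors) {
  if (nrow(data) == 0) {
    mur_stop("Empty data: cannot fit a tree.", class = "murtree_error_domain")
  }
  y <- data[[outcome]]
  if (is.null(y) || !is.numeric(y)) {
    mur_stop(sprintf("Outcome '%s' must be a numeric column.", outcome),
             class = "murtree_error_domain")
  }
  if (anyNA(y)) {
    mur_stop("Outcome contains missing values.", class = "murtree_error_domain")
  }
  vars <- purrr::map(predictors, function(v) {
    col <- data[[v]]
    if (is.null(col)) {
      mur_stop(sprintf("Predictor '%s' not found in data.", v),
               class = "murtree_error_domain")
    }
    if (is.logical(col)) {
      col <- factor(ifelse(col, "true", "false"), levels = c("false", "true"))
    }
    if (is.character(col)) col <- factor(col)
    if (!is.factor(col)) {
      mur_stop(sprintf(
        "Predictor '%s' must be categorical (factor/character/logical).", v),
        class = "murtree_error_domain")
    }
    list(name = v, codes = as.integer(col), levels = levels(col),
         ordered = is.ordered(col))
  })
  names(vars) <- predictors
  list(y = y, vars = vars, n = length(y))
}

# All candidate left-side level index sets for k present levels.
# Nominal: every non-empty proper subset (2^k - 2 candidates; complements are
# scored identically and resolved by the lexicographic tie-break).
# Ordered: the k - 1 order-respecting prefixes.
candidate_masks <- function(k, ordered) {
  if (ordered) {
    return(outer(seq_len(k - 1), seq_len(k), FUN = ">="))
  }
  n_sub <- 2L^k - 2L
  if (n_sub <= 0) return(matrix(FALSE, 0, k))
  ids <- seq_len(n_sub)
  vapply(seq_len(k), function(b) bitwAnd(ids, 2L^(b - 1L)) > 0L,
         logical(n_sub))
}

# Best split of one variable within a node. Returns NULL when no admissible
# split reduces the SSE. `min_side` is the minimum child size (minbucket).
best_split_for_var <- function(y, codes, levels, ordered, idx, min_side = 1L) {
  yk <- y[idx]
  ck <- codes[idx]
  cnt <- tabulate(ck, nbins = length(levels))
  present <- which(cnt > 0L)
  if (length(present) < 2L) return(NULL)
  sums <- vapply(present, function(l) sum(yk[ck == l]), numeric(1))
  ns <- cnt[present]
  S <- sum(sums); N <- sum(ns)
  k <- length(present)
  masks <- candidate_masks(k, ordered)
  if (nrow(masks) == 0) return(NULL)
  sL <- as.numeric(masks %*% sums)
  nL <- as.numeric(masks %*% ns)
  ok <- nL >= min_side & (N - nL) >= min_side
  if (!any(ok)) return(NULL)
  red <- rep(-Inf, length(sL))
  red[ok] <- sL[ok]^2 / nL[ok] + (S - sL[ok])^2 / (N - nL[ok]) - S^2 / N
  best <- max(red)
  if (!is.finite(best) || best <= 1e-12) return(NULL)
  cand <- which(red >= best - 1e-9 * max(1, abs(best)))
  if (length(cand) > 1) {
    # deterministic tie-break: lexicographically smallest left level set
    keys <- vapply(cand, function(i) {
      paste(sort(levels[present[masks[i, ]]]), collapse = "\r")
    }, character(1))
    cand <- cand[order(keys)][1]
  } else {
    cand <- cand[1]
  }
  left_present <- present[masks[cand, ]]
  left_levels <- levels[left_present]
  right_levels <- levels[setdiff(present, left_present)]
  if (ordered) {
    # absent levels join the side below the cut: everything strictly below
    # the lowest observed right-side level routes left
    cutpos <- min(match(right_levels, levels)) - 1L
    left_levels <- levels[seq_len(cutpos)]
    right_levels <- setdiff(levels, left_levels)
  }
  list(variable = NA_character_, left_levels = left_levels,
       right_levels = right_levels, sse_reduction = red[cand],
       n_left = as.integer(nL[cand]), n_right = as.integer(N - nL[cand]))
}

#' Best binary split of a node for one predictor
#'
#' Searches every admissible binary partition of the predictor's observed
#' levels (all proper subsets for nominal predictors, order-respecting cuts
#' for ordered ones) and returns the partition maximizing the reduction in
#' the sum of squared errors of the outcome. Returns `NULL` when the outcome
#' is constant in the node or no partition is admissible.
#'
#' @param data Data frame holding the node's observations.
#' @param variable Name of the categorical predictor to split on.
#' @param outcome Name of the numeric outcome column (default `"ppr"`).
#' @param minbucket Minimum number of observations on each side.
#' @return A list with `variable`, `left_levels`, `right_levels`,
#'   `sse_reduction`, `n_left`, `n_right`, or `NULL`.
#' @export
best_split <- function(data, variable, outcome = "ppr", minbucket = 1L) {
  d <- make_design(data, outcome, variable)
  v <- d$vars[[variable]]
  if (d$n < 2) {
    mur_stop("Need at least 2 observations to split.",
             class = "murtree_error_domain")
  }
  out <- best_split_for_var(d$y, v$codes, v$levels, v$ordered,
                            seq_len(d$n), min_side = minbucket)
  if (is.null(out)) return(NULL)
  out$variable <- variable
  out
}

# Surrogate splits for a primary split at one node: for every other
# predictor, the level partition that best mimics the primary left/right
# assignment. Nominal surrogates assign each level to the direction taken by
# the majority of its cases (which is the agreement-optimal partition);
# ordered surrogates search order-respecting cuts in both orientations.
# Surrogates whose agreement does not beat the majority-direction baseline
# are discarded; the survivors are ranked by agreement.
find_surrogates <- function(design, idx, primary_var, goes_left,
                            max_surrogates = 5L) {
  n <- length(idx)
  n_left <- sum(goes_left)
  baseline <- max(n_left, n - n_left) / n
  out <- list()
  for (v in names(design$vars)) {
    if (v == primary_var) next
    var <- design$vars[[v]]
    ck <- var$codes[idx]
    cnt <- tabulate(ck, nbins = length(var$levels))
    present <- which(cnt > 0L)
    if (length(present) < 2L) next
    left_cnt <- vapply(present, function(l) sum(goes_left[ck == l]),
                       numeric(1))
    tot_cnt <- cnt[present]
    if (var$ordered) {
      k <- length(present)
      cum_left <- cumsum(left_cnt)
      cum_tot <- cumsum(tot_cnt)
      # cases matched if prefix -> left: left cases in prefix + right cases in suffix
      agree_fwd <- cum_left[seq_len(k - 1)] +
        ((n - n_left) - (cum_tot[seq_len(k - 1)] - cum_left[seq_len(k - 1)]))
      # prefix -> right orientation
      agree_bwd <- (cum_tot[seq_len(k - 1)] - cum_left[seq_len(k - 1)]) +
        (n_left - cum_left[seq_len(k - 1)])
      best_fwd <- which.max(agree_fwd)
      best_bwd <- which.max(agree_bwd)
      if (agree_fwd[best_fwd] >= agree_bwd[best_bwd]) {
        cutpos <- present[best_fwd]
        left_levels <- var$levels[seq_len(cutpos)]
        agree_n <- agree_fwd[best_fwd]
      } else {
        cutpos <- present[best_bwd]
        left_levels <- setdiff(var$levels, var$levels[seq_len(cutpos)])
        agree_n <- agree_bwd[best_bwd]
      }
      right_levels <- setdiff(var$levels, left_levels)
    } else {
      to_left <- left_cnt > tot_cnt - left_cnt |
        (left_cnt == tot_cnt - left_cnt & n_left >= n - n_left)
      left_levels <- var$levels[present[to_left]]
      right_levels <- var$levels[present[!to_left]]
      agree_n <- sum(pmax(left_cnt, tot_cnt - left_cnt))
    }
    if (length(left_levels) == 0 || length(right_levels) == 0) next
    agreement <- agree_n / n
    if (agreement <= baseline + 1e-12) next
    out[[length(out) + 1]] <- list(variable = v, left_levels = left_levels,
                                   right_levels = right_levels,
                                   agreement = agreement)
  }
  if (length(out) == 0) return(list())
  ord <- order(-vapply(out, `[[`, numeric(1), "agreement"))
  out[ord][seq_len(min(length(out), max_surrogates))]
}
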