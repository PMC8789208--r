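# Fixture builders and independent oracles used across the suite. Oracles
# compute expected values from first principles (direct SSE sums, subset
# enumeration via combn) so they share no code with the engine.

make_edition <- function(event_id = "ev_2010", attendance = 10000,
                         first_day = as.Date("2010-07-02"), n_days = 1,
                         category = "outdoor_music", indoor = FALSE,
                         sold_out = FALSE, year = 2010) {
  tibble::tibble(
    event_id = event_id, series_name = sub("_[0-9]+$", "", event_id),
    year = year, category = category, attendance = attendance,
    first_day = first_day, n_days = n_days, timing = "day_and_night",
    indoor = indoor, bounded = TRUE, camping = FALSE, alcohol = "unlimited",
    hospital_distance_km = 5, hospital_time_min = 10, sold_out = sold_out
  )
}

make_encounters <- function(event_id, days, dismissal = "back_to_event",
                            age = 25) {
  n <- length(days)
  tibble::tibble(
    event_id = rep(event_id, n), day = as.Date(days),
    age = rep_len(age, n), dismissal = rep_len(dismissal, n),
    triage = rep("green", n)
  )
}

# a small event table for tree fixtures: outcome driven by `g1`
# (2 levels), refined by `g2` within one branch, plus an inert predictor
tree_fixture <- function(n_per = 5, means = c(a1 = 10, a2 = 30, b = 80),
                         noise = 0, seed = 99) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    d <- tibble::tibble(
      g1 = rep(c("a", "a", "b"), each = n_per),
      g2 = rep(c("x", "y", "x"), each = n_per),
      inert = sample(c("p", "q"), 3 * n_per, replace = TRUE),
      y = rep(c(means[["a1"]], means[["a2"]], means[["b"]]), each = n_per) +
        rnorm(3 * n_per, 0, noise)
    )
    d$g1 <- factor(d$g1); d$g2 <- factor(d$g2); d$inert <- factor(d$inert)
    d
  })
}

# independent split oracle: direct SSE definition, subsets via combn
oracle_best_reduction <- function(y, x, ordered = FALSE) {
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  lev <- if (ordered) levels(factor(x)) else sort(unique(as.character(x)))
  lev <- lev[lev %in% as.character(x)]
  k <- length(lev)
  if (k < 2) return(NULL)
  best <- NULL
  if (ordered) {
    subsets <- lapply(seq_len(k - 1), function(j) lev[seq_len(j)])
  } else {
    subsets <- unlist(lapply(seq_len(k - 1), function(m)
      utils::combn(lev, m, simplify = FALSE)), recursive = FALSE)
  }
  for (s in subsets) {
    left <- as.character(x) %in% s
    if (!any(left) || all(left)) next
    red <- sse(y) - sse(y[left]) - sse(y[!left])
    if (is.null(best) || red > best$reduction + 1e-12) {
      best <- list(reduction = red, left = sort(s))
    }
  }
  best
}

# sort-by-node-mean search (Fisher ordering): optimal for nominal splits
sorted_mean_best_reduction <- function(y, x) {
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  means <- tapply(y, as.character(x), mean)
  lev <- names(sort(means))
  if (length(lev) < 2) return(NULL)
  best <- -Inf
  for (j in seq_len(length(lev) - 1)) {
    left <- as.character(x) %in% lev[seq_len(j)]
    best <- max(best, sse(y) - sse(y[left]) - sse(y[!left]))
  }
  best
}

# event table whose predictors are plain factors, for engine-level tests
random_fixture <- function(n = 10, k_levels = 3, n_vars = 2, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(y = round(runif(n, 0, 100), 1))
  for (v in seq_len(n_vars)) {
    lev <- letters[seq_len(k_levels)]
    x <- sample(lev, n, replace = TRUE)
    x[1:2] <- lev[1:2]  # at least two observed levels
    d[[paste0("v", v)]] <- factor(x, levels = lev)
  }
  d
}

default_registry <- function(seed = 1, ...) {
  generate_registry(synth_config(seed = seed, ...))
}

# a different world for external-validation degradation checks: the same
# rates re-assigned so that development-model predictions are uncorrelated
# with the new truth (sports extreme, EDM mild, music moderate)
default_true_effects_scrambled <- function() {
  e <- murtree:::default_true_effects()
  e$true_ppr <- c(120, 120, 273, 12, 225, 64, 176)
  e
}
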