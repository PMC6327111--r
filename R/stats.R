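get_counts <- function(counts) {
  if (is.data.frame(counts)) {
    if (!"count" %in% names(counts)) abort("data frame must have a `count` column")
    counts <- counts$count
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    abort("counts must be non-negative integers")
  }
  if (length(counts) < 2) abort("need at least 2 bins")
  as.numeric(counts)
}

#' Variance-to-mean ratio of per-bin counts
#'
#' Overdispersion index of counts in equal tubule-length bins:
#' `(<n^2> - <n>^2) / <n>` with population moments (divisor N).  A value
#' of 1 indicates spatial randomness (Poisson), values above 1 clustering;
#' homeostatic spermatogonial counts show a ratio of about 3.  A
#' sample-variance (divisor N-1) variant is exposed via `sample_variance`.
#'
#' @param counts Integer vector or data frame with a `count` column
#'   (e.g. [bin_counts()] output).
#' @param sample_variance Use divisor N-1 instead of N.
#' @return The ratio (numeric scalar).
#' @examples
#' variance_to_mean(c(1, 3))  # 0.5
#' @export
variance_to_mean <- function(counts, sample_variance = FALSE) {
  n <- get_counts(counts)
  mu <- mean(n)
  if (mu == 0) abort("all counts are zero: variance-to-mean ratio undefined")
  v <- if (sample_variance) stats::var(n) else mean(n^2) - mu^2
  v / mu
}

#' Chi-square goodness of fit against a Poisson distribution
#'
#' Tests whether per-bin counts are consistent with complete spatial
#' randomness: the histogram of count values is compared with the Poisson
#' pmf at the sample mean.  Adjacent cells in each tail are pooled until
#' every expected count is at least `min_expected`; degrees of freedom are
#' `cells - 1 - 1` (one for the estimated mean).  The p-value is the upper
#' tail of the chi-square distribution.
#'
#' @inheritParams variance_to_mean
#' @param min_expected Pooling threshold for expected cell counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_cells`
#'   (after pooling), `mean`, `n_bins`.
#' @export
poisson_gof <- function(counts, min_expected = 5) {
  n <- get_counts(counts)
  if (length(n) < 20) warn("fewer than 20 bins: chi-square approximation may be poor")
  mu <- mean(n)
  if (mu == 0) abort("all counts are zero: test undefined")
  kmax <- max(n)
  obs <- tabulate(n + 1, nbins = kmax + 1)          # counts of value 0..kmax
  expd <- dpois(0:kmax, mu) * length(n)
  expd[kmax + 1] <- expd[kmax + 1] + stats::ppois(kmax, mu, lower.tail = FALSE) * length(n)

  # pool lower tail upward, upper tail downward, until expected >= threshold
  pool <- function(o, e) {
    while (length(e) > 1 && e[1] < min_expected) {
      o[2] <- o[2] + o[1]; e[2] <- e[2] + e[1]
      o <- o[-1]; e <- e[-1]
    }
    while (length(e) > 1 && e[length(e)] < min_expected) {
      k <- length(e)
      o[k - 1] <- o[k - 1] + o[k]; e[k - 1] <- e[k - 1] + e[k]
      o <- o[-k]; e <- e[-k]
    }
    list(o = o, e = e)
  }
  p <- pool(obs, expd)
  if (length(p$e) < 3) abort("fewer than 3 pooled cells: test undefined")
  stat <- sum((p$o - p$e)^2 / p$e)
  df <- length(p$e) - 2L
  tibble::tibble(
    statistic = stat, df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE),
    n_cells = length(p$e), mean = mu, n_bins = length(n)
  )
}

validate_category_table <- function(table) {
  need <- c("category", "length_fraction", "observed")
  if (!all(need %in% names(table))) {
    abort("category table needs columns category, length_fraction, observed")
  }
  f <- table$length_fraction
  if (any(f <= 0) || any(f >= 1) || abs(sum(f) - 1) > 1e-9) {
    abort("length fractions must lie in (0,1) and sum to 1")
  }
  if (any(table$observed < 0)) abort("observed counts must be >= 0")
  if ("boundary_observed" %in% names(table) &&
      any(table$boundary_observed < 0, na.rm = TRUE)) {
    abort("boundary counts must be >= 0")
  }
  invisible(table)
}

#' Positional preference of cells among tubule categories
#'
#' For each positional category (e.g. adjacent / not adjacent to a mitogen
#' source region) the expected cell count under unbiased placement is the
#' total count times the category's share of tubule circumference length;
#' the preference is observed / expected, so 1 means no bias, above 1
#' attraction, below 1 avoidance.  Cells scored "boundary" (partially
#' adjacent) are split 0.5/0.5 between the two categories before analysis
#' (two-category tables only).  The departure from uniformity is evaluated
#' by a chi-square test, `sum((obs - exp)^2 / exp)` with
#' `df = categories - 1`, computed on the (possibly non-integer)
#' boundary-adjusted observed counts; set `round_adjusted = TRUE` to round
#' them first, or `exact = TRUE` for an exact multinomial test on integer
#' counts (small tables).
#'
#' @param table Data frame with columns `category`, `length_fraction`,
#'   `observed` and optionally `boundary_observed`.
#' @param round_adjusted Round boundary-adjusted counts to integers before
#'   the chi-square statistic.
#' @param exact Use an exact multinomial test instead of the chi-square
#'   approximation (requires integer adjusted counts and a small total).
#' @return Object of class `mito_preference`; [tidy()] returns the
#'   per-category table with expected counts and preference ratios,
#'   [glance()] the test statistic, df and p-value.
#' @examples
#' tbl <- tibble::tibble(category = c("positive", "negative"),
#'                       length_fraction = c(0.4, 0.6), observed = c(4, 6))
#' preference(tbl)
#' @export
preference <- function(table, round_adjusted = FALSE, exact = FALSE) {
  validate_category_table(table)
  obs <- as.numeric(table$observed)
  boundary_total <- if ("boundary_observed" %in% names(table)) {
    sum(table$boundary_observed, na.rm = TRUE)
  } else 0
  if (boundary_total > 0) {
    if (nrow(table) != 2) {
      abort("boundary splitting is defined only for two-category tables")
    }
    obs <- obs + boundary_total / 2
  }
  total <- sum(obs)
  if (total <= 0) abort("total observed count must be positive")
  expd <- total * table$length_fraction
  if (any(expd <= 0)) abort("zero expected count in a category")
  if (round_adjusted) obs <- round(obs)

  pref <- obs / expd
  if (exact) {
    if (any(abs(obs - round(obs)) > 1e-9)) {
      abort("exact multinomial test requires integer adjusted counts (set round_adjusted = TRUE)")
    }
    stat <- NA_real_; df <- NA_integer_
    p <- multinomial_exact_p(round(obs), table$length_fraction)
    method <- "exact multinomial"
  } else {
    stat <- sum((obs - expd)^2 / expd)
    df <- nrow(table) - 1L
    p <- pchisq(stat, df, lower.tail = FALSE)
    method <- "chi-square"
  }
  structure(
    list(
      table = tibble::tibble(
        category = table$category,
        length_fraction = table$length_fraction,
        observed_adjusted = obs, expected = expd, preference = pref
      ),
      statistic = stat, df = df, p_value = p, method = method,
      boundary_total = boundary_total
    ),
    class = "mito_preference"
  )
}

# exact multinomial p: sum of probabilities of outcomes at least as extreme
# (by probability ordering) as the observed one; enumerated, so small totals
multinomial_exact_p <- function(obs, prob) {
  total <- sum(obs)
  if (total > 200) abort("exact test limited to totals <= 200")
  k <- length(obs)
  if (k == 2) {
    probs <- stats::dbinom(0:total, total, prob[1])
    p_obs <- stats::dbinom(obs[1], total, prob[1])
    return(sum(probs[probs <= p_obs + 1e-12]))
  }
  grid <- as.matrix(expand.grid(rep(list(0:total), k - 1)))
  grid <- grid[rowSums(grid) <= total, , drop = FALSE]
  cnt <- cbind(grid, total - rowSums(grid))
  pr <- apply(cnt, 1, function(x) stats::dmultinom(x, total, prob))
  p_obs <- stats::dmultinom(obs, total, prob)
  sum(pr[pr <= p_obs + 1e-12])
}

#' @export
print.mito_preference <- function(x, ...) {
  cat("<mito_preference> (", x$method, ")\n", sep = "")
  print(as.data.frame(x$table), row.names = FALSE)
  if (!is.na(x$statistic)) {
    cat(sprintf("  chi-square = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("  exact multinomial p = %.4g\n", x$p_value))
  }
  invisible(x)
}

#' @export
tidy.mito_preference <- function(x, ...) x$table

#' @export
glance.mito_preference <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 method = x$method, boundary_total = x$boundary_total)
}
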