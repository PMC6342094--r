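# Core statistics for intersexual fitness correlations.

# Fast unvalidated product-moment core shared by pearson_rmf() and the
# scenario simulator. Returns a plain list; callers validate inputs.
# Slope and its SE are for the regression of y (female) on x (male).
.pearson_core <- function(x, y) {
  n <- length(x)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx <= 0 || syy <= 0) {
    return(list(
      r = NA_real_, t_stat = NA_real_, df = n - 2L, p_two_tailed = NA_real_,
      slope = NA_real_, slope_se = NA_real_, n = n
    ))
  }
  sxy <- sum(dx * dy)
  r <- sxy / sqrt(sxx * syy)
  # clamp rounding overshoot so downstream sqrt(1 - r^2) stays real
  r <- max(-1, min(1, r))
  df <- n - 2L
  t_stat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t_stat), df)
  slope <- sxy / sxx
  rss <- syy - slope * sxy
  slope_se <- sqrt(max(rss, 0) / (df * sxx))
  list(
    r = r, t_stat = t_stat, df = df, p_two_tailed = p,
    slope = slope, slope_se = slope_se, n = n
  )
}

#' Pearson intersexual correlation with t-based significance
#'
#' Computes the product-moment correlation between paired male and female
#' fitness values (one pair per genotype), the t statistic
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} with \eqn{n-2} degrees of freedom, its
#' two-tailed p-value, and the ordinary least-squares slope (with standard
#' error) of the regression of female fitness on male fitness. In simple
#' regression the slope's t statistic is identical to the correlation's, so
#' the returned p-value tests both.
#'
#' @param male_values,female_values Numeric vectors of equal length
#'   (\eqn{n \ge 3}), one value per genotype, both with nonzero variance.
#'
#' @return A one-row tibble with columns `r`, `t_stat`, `df`,
#'   `p_two_tailed`, `slope`, `slope_se`, `n`.
#'
#' @examples
#' pearson_rmf(c(2, 4, 6, 8), c(1, 3, 2, 5))
#' @export
pearson_rmf <- function(male_values, female_values) {
  if (!is.numeric(male_values) || !is.numeric(female_values)) {
    abort("`male_values` and `female_values` must be numeric vectors.")
  }
  if (length(male_values) != length(female_values)) {
    abort("`male_values` and `female_values` must have the same length.")
  }
  if (anyNA(male_values) || anyNA(female_values)) {
    abort("missing values are not allowed; drop or impute them first.")
  }
  n <- length(male_values)
  if (n < 3) {
    abort(sprintf("need at least 3 pairs to correlate, got %d.", n))
  }
  res <- .pearson_core(male_values, female_values)
  if (is.na(res$r)) {
    zero <- if (sd(male_values) == 0) "male_values" else "female_values"
    abort(sprintf("correlation undefined: `%s` has zero variance.", zero))
  }
  tibble::new_tibble(res, nrow = 1L)
}

#' Compare two regression slopes
#'
#' Tests whether two independently estimated regression slopes differ, using
#' \eqn{t = (b_1 - b_2) / \sqrt{s_{b_1}^2 + s_{b_2}^2}} on
#' \eqn{n_1 + n_2 - 4} degrees of freedom (two slopes and two intercepts
#' estimated). Used to compare the male-female fitness regression with and
#' without suspect (CI-affected) lines.
#'
#' @param b1,b2 The two slope estimates.
#' @param se1,se2 Their standard errors (nonnegative, not both zero unless
#'   the slopes are equal).
#' @param n1,n2 The number of observations behind each slope (both >= 3).
#'
#' @return A one-row tibble with columns `b1`, `b2`, `se1`, `se2`, `t_stat`,
#'   `df`, `p_two_tailed`. If both standard errors are zero and the slopes
#'   differ, `t_stat` is signed infinity (with a warning) and the p-value 0.
#'
#' @examples
#' compare_slopes(b1 = 1, se1 = 0.5, n1 = 27, b2 = 0, se2 = 0.5, n2 = 25)
#' @export
compare_slopes <- function(b1, se1, n1, b2, se2, n2) {
  for (nm in c("b1", "se1", "n1", "b2", "se2", "n2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort(sprintf("`%s` must be a single non-missing number.", nm))
    }
  }
  if (se1 < 0 || se2 < 0) abort("slope standard errors must be nonnegative.")
  if (n1 < 3 || n2 < 3) abort("each regression needs at least 3 observations.")
  pooled_se <- sqrt(se1^2 + se2^2)
  df <- as.integer(n1 + n2 - 4)
  if (pooled_se == 0) {
    if (b1 == b2) {
      t_stat <- 0
    } else {
      warn("both slope SEs are zero with unequal slopes: t is infinite.")
      t_stat <- sign(b1 - b2) * Inf
    }
  } else {
    t_stat <- (b1 - b2) / pooled_se
  }
  tibble::tibble(
    b1 = b1, b2 = b2, se1 = se1, se2 = se2,
    t_stat = t_stat, df = df, p_two_tailed = 2 * pt(-abs(t_stat), df)
  )
}

#' Tally replicate correlations by sign and significance
#'
#' Summarizes a table of per-replicate correlation results into the four
#' counts used to report simulation scenarios: positive, negative,
#' significant-positive, and significant-negative correlations. A correlation
#' of exactly zero counts as positive; undefined correlations (`NA` from
#' zero-variance replicates) are excluded from all four counts and reported
#' separately.
#'
#' @param results A data frame with at least columns `r` and `p_two_tailed`,
#'   one row per replicate (as returned by [pearson_rmf()] or stored in a
#'   scenario summary).
#' @param alpha Two-tailed significance level (default 0.05).
#'
#' @return A one-row tibble with columns `n_positive`, `n_negative`,
#'   `n_sig_positive`, `n_sig_negative`, `n_undefined`.
#'
#' @export
tally_correlations <- function(results, alpha = 0.05) {
  if (!is.data.frame(results)) abort("`results` must be a data frame.")
  if (nrow(results) == 0) {
    return(tibble::tibble(
      n_positive = 0L, n_negative = 0L,
      n_sig_positive = 0L, n_sig_negative = 0L, n_undefined = 0L
    ))
  }
  if (!all(c("r", "p_two_tailed") %in% names(results))) {
    abort("`results` must have columns `r` and `p_two_tailed`.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  r <- results$r
  p <- results$p_two_tailed
  ok <- !is.na(r)
  pos <- ok & r >= 0
  neg <- ok & r < 0
  sig <- ok & !is.na(p) & p < alpha
  tibble::tibble(
    n_positive = sum(pos),
    n_negative = sum(neg),
    n_sig_positive = sum(sig & pos),
    n_sig_negative = sum(sig & neg),
    n_undefined = sum(!ok)
  )
}

#' Pearson chi-square test of independence
#'
#' Tests independence of rows and columns in a two-dimensional contingency
#' table with the Pearson statistic \eqn{\sum (O - E)^2 / E}, expected counts
#' from the row and column margins, and no continuity correction.
#'
#' @param table A numeric matrix of nonnegative counts with at least two rows
#'   and two columns; every row and column sum must be positive.
#'
#' @return A one-row tibble with columns `chi2`, `df`, `p_value`.
#'
#' @examples
#' chi_square_independence(matrix(c(3, 7, 7, 3), nrow = 2, byrow = TRUE))
#' @export
chi_square_independence <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table) || !is.numeric(table)) {
    abort("`table` must be a numeric matrix of counts.")
  }
  if (anyNA(table) || any(table < 0)) {
    abort("all counts must be nonnegative and non-missing.")
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("`table` must have at least 2 rows and 2 columns.")
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0)) abort(sprintf("row %d of `table` is empty.", which(rs == 0)[1]))
  if (any(cs == 0)) abort(sprintf("column %d of `table` is empty.", which(cs == 0)[1]))
  fit <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(
    chi2 = unname(fit$statistic),
    df = as.integer(unname(fit$parameter)),
    p_value = unname(fit$p.value)
  )
}

#' Binomial sign test with normal z statistic
#'
#' Tests an observed split of `k` successes in `n` trials against a null
#' success probability `p0`, reporting both the normal-approximation
#' statistic \eqn{z = (k - n p_0)/\sqrt{n p_0 (1 - p_0)}} (no continuity
#' correction) and the exact two-sided p-value obtained by summing all
#' binomial point masses no larger than that of `k`. Used for splits of
#' significant-negative versus significant-positive correlations.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param p0 Null success probability, strictly between 0 and 1
#'   (default 0.5).
#'
#' @return A one-row tibble with columns `k`, `n`, `p0`, `z`, `p_exact`.
#'
#' @examples
#' binomial_sign_test(18, 18)
#' @export
binomial_sign_test <- function(k, n, p0 = 0.5) {
  for (nm in c("k", "n", "p0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort(sprintf("`%s` must be a single non-missing number.", nm))
    }
  }
  if (n < 1 || n != round(n)) abort("`n` must be a positive integer.")
  if (k < 0 || k > n || k != round(k)) abort("`k` must be an integer in [0, n].")
  if (p0 <= 0 || p0 >= 1) abort("`p0` must be strictly between 0 and 1.")
  z <- (k - n * p0) / sqrt(n * p0 * (1 - p0))
  p_exact <- binom.test(k, n, p = p0)$p.value
  tibble::tibble(k = as.integer(k), n = as.integer(n), p0 = p0, z = z, p_exact = p_exact)
}
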