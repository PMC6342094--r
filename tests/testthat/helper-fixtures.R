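# Small fixtures built in code, shared across test files.

# A balanced toy record set: deterministic values, 3 lines x 2 blocks x
# 2 per sex per block. Values are chosen so no sex-by-block cell is constant.
toy_records <- function() {
  grid <- tidyr::expand_grid(
    line_id = c("A", "B", "C"),
    sex = c("F", "M"),
    block = c("B1", "B2"),
    individual = c("i1", "i2")
  )
  grid$fitness <- c(
    4, 6, 5, 9, 2, 4, 3, 5, # line A: F(B1,B1,B2,B2), M(B1,B1,B2,B2)
    10, 14, 11, 15, 6, 10, 7, 11, # line B
    20, 26, 23, 27, 12, 16, 13, 19 # line C
  )
  grid
}

# Random balanced records with no line or interaction structure (pure
# block + residual noise), for null calibration of the interaction test.
null_records <- function(n_lines = 8, n_blocks = 2, n_per = 5) {
  d <- tidyr::expand_grid(
    line_id = sprintf("L%02d", seq_len(n_lines)),
    sex = c("F", "M"),
    block = sprintf("B%d", seq_len(n_blocks)),
    individual = seq_len(n_per)
  )
  b <- rnorm(n_blocks)
  d$fitness <- rnorm(nrow(d)) + b[as.integer(factor(d$block))]
  d
}

# Brute-force Pearson chi-square oracle: expected counts from margins,
# sum of (O - E)^2 / E computed with explicit loops.
chisq_oracle <- function(tab) {
  total <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / total
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# Exact two-sided binomial p by full pmf enumeration: sum of all point
# masses not exceeding the observed one (with a relative tolerance for
# floating-point ties, as in the classical exact test).
binom_oracle_p <- function(k, n, p0 = 0.5) {
  pm <- dbinom(0:n, n, p0)
  sum(pm[pm <= pm[k + 1] * (1 + 1e-7)])
}
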