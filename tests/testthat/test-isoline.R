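test_that("standardize_fitness zeroes and unit-scales every sex-block cell", {
  z <- standardize_fitness(toy_records())
  cells <- z |>
    dplyr::group_by(sex, block) |>
    dplyr::summarise(m = mean(fitness_z), s = sd(fitness_z), .groups = "drop")
  expect_true(all(abs(cells$m) < 1e-9))
  expect_true(all(abs(cells$s - 1) < 1e-9))
  # raw values retained
  expect_equal(z$fitness, toy_records()$fitness)
})

test_that("standardize_fitness matches the hand-computed two-value cell", {
  rec <- tibble::tibble(
    line_id = c("A", "B"), sex = "F", block = "B1",
    individual = c("i1", "i2"), fitness = c(4, 6)
  )
  z <- standardize_fitness(rec)
  # sample SD = sqrt(2), so z = (-1/sqrt(2), +1/sqrt(2))
  expect_equal(z$fitness_z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("standardization is invariant to cell-wise location shifts", {
  rec <- toy_records()
  shifted <- dplyr::mutate(
    rec,
    fitness = fitness + ifelse(sex == "F" & block == "B2", 100, 0)
  )
  expect_equal(
    standardize_fitness(rec)$fitness_z,
    standardize_fitness(shifted)$fitness_z,
    tolerance = 1e-12
  )
})

test_that("standardize_fitness names the offending degenerate cell", {
  rec <- toy_records()
  const <- dplyr::mutate(
    rec,
    fitness = ifelse(sex == "M" & block == "B2", 7, fitness)
  )
  expect_error(standardize_fitness(const), "sex = M, block = B2")
  lone <- tibble::tibble(
    line_id = "A", sex = c("F", "F", "M"), block = "B1",
    individual = c("i1", "i2", "i3"), fitness = c(4, 6, 5)
  )
  expect_error(standardize_fitness(lone), "fewer than 2")
})

test_that("flag_outliers applies the |z| > k rule without removing anything", {
  z <- standardize_fitness(toy_records())
  expect_equal(nrow(flag_outliers(z, k = 3)), 0L)
  expect_equal(nrow(flag_outliers(z, k = 1.2)), sum(abs(z$fitness_z) > 1.2))
  # threshold is strict
  z2 <- z
  z2$fitness_z[1] <- 5.2
  flagged <- flag_outliers(z2, k = 3)
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$individual, z2$individual[1])
})

test_that("flag_outliers flags about 2 * pnorm(-k) of standard-normal data", {
  set.seed(8)
  n <- 1000
  rec <- tibble::tibble(
    line_id = "L1", sex = rep(c("F", "M"), each = n / 2),
    block = "B1", individual = as.character(seq_len(n)),
    fitness = rnorm(n)
  )
  flagged <- flag_outliers(standardize_fitness(rec), k = 2)
  # expectation about 45.5; allow a generous binomial band
  expect_gt(nrow(flagged), 20)
  expect_lt(nrow(flagged), 75)
})

test_that("line_sex_means aggregates per line and is order-invariant", {
  z <- standardize_fitness(toy_records())
  means <- line_sex_means(z)
  expect_equal(nrow(means), 3L)
  expect_equal(means$n_male, rep(4L, 3))
  expect_equal(
    means$mean_female_z[means$line_id == "A"],
    mean(z$fitness_z[z$line_id == "A" & z$sex == "F"])
  )
  shuffled <- z[sample(nrow(z)), ]
  expect_equal(means, line_sex_means(shuffled))
  # missing sex is an error naming the line
  expect_error(line_sex_means(z[!(z$line_id == "B" & z$sex == "M"), ]), "B")
})

test_that("a full-design dataset yields one line mean per line", {
  d <- isoline_design()
  rec <- generate_isolines(d, seed = 21)
  means <- line_sex_means(standardize_fitness(rec))
  expect_equal(nrow(means), 27L)
  expect_equal(means$n_male, rep(30L, 27))
})

test_that("estimate_rmf re-standardizes after exclusion", {
  d <- isoline_design(ci_lines = c("L07", "L12"))
  rec <- generate_isolines(d, seed = 9)

  # consistency: no exclusion equals the two-step pipeline
  means <- line_sex_means(standardize_fitness(rec))
  direct <- pearson_rmf(means$mean_male_z, means$mean_female_z)
  est <- estimate_rmf(rec)
  expect_equal(est$r, direct$r, tolerance = 1e-12)
  expect_equal(est$df, 25L)

  # excluding the CI lines re-standardizes: different from naive
  # subsetting of the old z-scores
  excl <- estimate_rmf(rec, exclude_lines = c("L07", "L12"))
  expect_equal(excl$n, 25L)
  expect_equal(excl$df, 23L)
  naive <- means[!means$line_id %in% c("L07", "L12"), ]
  naive_r <- pearson_rmf(naive$mean_male_z, naive$mean_female_z)$r
  expect_gt(abs(excl$r - naive_r), 1e-6)

  # record order and block relabeling leave the estimate unchanged
  shuffled <- rec[sample(nrow(rec)), ]
  relabeled <- dplyr::mutate(
    shuffled,
    block = c(B1 = "blockC", B2 = "blockA", B3 = "blockB")[block]
  )
  expect_equal(estimate_rmf(relabeled)$r, est$r, tolerance = 1e-12)

  expect_error(
    estimate_rmf(rec, exclude_lines = sprintf("L%02d", 1:25)),
    "at least 3 lines"
  )
})

test_that("interaction_f_test matches a balanced sums-of-squares oracle", {
  set.seed(31)
  # balanced fixture: 4 lines x 2 sexes x 2 blocks x 3 replicates
  d <- tidyr::expand_grid(
    line_id = c("A", "B", "C", "D"),
    sex = c("F", "M"),
    block = c("B1", "B2"),
    individual = 1:3
  )
  d$fitness <- rnorm(nrow(d), sd = 2)
  z <- standardize_fitness(d)

  got <- interaction_f_test(z)

  # independent oracle: orthogonal (balanced) decomposition from cell means
  y <- z$fitness_z
  n_rep <- 6 # per sex-line cell (2 blocks x 3)
  grand <- mean(y)
  cell <- tapply(y, list(z$sex, z$line_id), mean)
  sex_m <- tapply(y, z$sex, mean)
  line_m <- tapply(y, z$line_id, mean)
  block_m <- tapply(y, z$block, mean)
  ss_int <- n_rep * sum((cell - outer(sex_m - grand, line_m - grand, "+") -
    grand)^2)
  ss_sex <- 24 * sum((sex_m - grand)^2)
  ss_line <- 12 * sum((line_m - grand)^2)
  ss_block <- 24 * sum((block_m - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_sex - ss_line - ss_block - ss_int
  df1 <- (2 - 1) * (4 - 1)
  df2 <- nrow(d) - (1 + 1 + 3 + 1 + 3) # N - rank of the full model
  f_oracle <- (ss_int / df1) / (ss_res / df2)

  expect_equal(got$F_stat, f_oracle, tolerance = 1e-8)
  expect_equal(got$df1, df1)
  expect_equal(got$df2, as.integer(df2))
  expect_equal(got$p_value, pf(f_oracle, df1, df2, lower.tail = FALSE),
    tolerance = 1e-8
  )
})

test_that("interaction_f_test has power against injected sex-by-line effects", {
  set.seed(17)
  # the assay's replication: 3 blocks x 10 per sex per line
  rejections <- purrr::map_lgl(1:40, function(i) {
    d <- null_records(n_lines = 8, n_blocks = 3, n_per = 10)
    # push two lines in opposite directions in the two sexes: 1 SD effect
    shift <- ifelse(d$line_id %in% c("L01", "L02"),
      ifelse(d$sex == "M", 0.5, -0.5), 0
    )
    shift <- shift * ifelse(d$line_id == "L02", -1, 1)
    d$fitness <- d$fitness + shift
    interaction_f_test(standardize_fitness(d))$p_value < 0.05
  })
  expect_gt(mean(rejections), 0.9)
})

test_that("interaction_f_test validates structure and names empty cells", {
  z <- standardize_fitness(toy_records())
  missing_cell <- z[!(z$line_id == "C" & z$sex == "M"), ]
  expect_error(interaction_f_test(missing_cell), "\\(M, C\\)")
  one_block <- dplyr::mutate(z, block = "B1")
  expect_error(interaction_f_test(one_block), "2 blocks")
})

test_that("duplicating every record grows df2 but not the conclusion", {
  set.seed(77)
  d <- null_records(n_lines = 6, n_blocks = 2, n_per = 4)
  z <- standardize_fitness(d)
  a <- interaction_f_test(z)
  doubled <- dplyr::bind_rows(z, dplyr::mutate(z, individual = individual + 100))
  b <- interaction_f_test(doubled)
  expect_equal(b$df2, 2L * nrow(z) - (nrow(z) - a$df2))
  expect_equal(a$df1, b$df1)
})

test_that("ci_bias_report bundles the exclusion diagnostics", {
  d <- isoline_design(ci_lines = c("L07", "L12"))
  rec <- generate_isolines(d, seed = 4)
  rep <- ci_bias_report(rec, suspect_lines = c("L07", "L12"))

  expect_s3_class(rep, "ci_bias_report")
  expect_equal(nrow(rep$leverage), 27L)
  expect_equal(sort(rep$leverage$line_id), sort(unique(rec$line_id)))
  g <- glance(rep)
  expect_equal(g$n_suspect, 2L)
  expect_equal(g$slope_df, 48L)
  td <- tidy(rep)
  expect_equal(sum(td$suspect), 2L)
  # CI lines: among the best male ranks, the worst female ranks
  expect_true(all(td$rank_female[td$suspect] >= 26))
  expect_true(all(td$rank_male[td$suspect] <= 5))

  # empty suspect set: identical fits, slope t of 0
  none <- ci_bias_report(rec, suspect_lines = character())
  expect_equal(none$with_suspects$r, none$without_suspects$r)
  expect_equal(none$slope_comparison$t_stat, 0)

  expect_error(ci_bias_report(rec, "L99"), "L99")
})

test_that("report plots and scenario plots build", {
  d <- isoline_design(ci_lines = "L03", n_lines = 8)
  rec <- generate_isolines(d, seed = 2)
  p1 <- autoplot(ci_bias_report(rec, "L03"))
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(run_scenario(scenario_config(n_replicates = 20), seed = 1))
  expect_s3_class(p2, "ggplot")
})
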