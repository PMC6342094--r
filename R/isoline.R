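# Isofemale-line analysis pipeline: standardize, aggregate, correlate,
# exclude suspect lines, compare slopes, interaction test.

check_fitness_records <- function(records, need_z = FALSE) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  need <- c("line_id", "sex", "block", "fitness")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  bad_sex <- !records$sex %in% c("M", "F")
  if (any(bad_sex)) {
    abort(sprintf(
      "`sex` must be \"M\" or \"F\"; found %s (first offending row %d).",
      paste(utils::head(unique(records$sex[bad_sex]), 3), collapse = ", "),
      which(bad_sex)[1]
    ))
  }
  if (!is.numeric(records$fitness)) abort("`fitness` must be numeric.")
  if (need_z && !"fitness_z" %in% names(records)) {
    abort("`records` must be standardized first; see standardize_fitness().")
  }
  invisible(records)
}

#' Z-standardize fitness within each sex-by-block cell
#'
#' Puts male and female fitness on a common scale by transforming raw
#' fitness to \eqn{z = (x - \bar{x}) / s} using the mean and sample standard
#' deviation (n-1 denominator) of each sex-within-block cell. Raw values are
#' retained alongside the standardized column.
#'
#' @param records A data frame of individual fitness records with columns
#'   `line_id`, `sex` (`"M"`/`"F"`), `block`, `fitness` (and any others,
#'   which are passed through). Every sex-by-block cell must contain at
#'   least two records with nonzero spread.
#'
#' @return The input tibble with a `fitness_z` column added (replaced if
#'   already present).
#'
#' @export
standardize_fitness <- function(records) {
  check_fitness_records(records)
  records <- tibble::as_tibble(records)
  if (anyNA(records$fitness)) {
    abort("`fitness` contains missing values; drop them before standardizing (read_fitness_csv() does this).")
  }
  cells <- records |>
    dplyr::group_by(.data$sex, .data$block) |>
    dplyr::summarise(
      cell_n = dplyr::n(),
      cell_mean = mean(.data$fitness),
      cell_sd = sd(.data$fitness),
      .groups = "drop"
    )
  bad <- cells$cell_n < 2 | cells$cell_sd == 0
  if (any(bad)) {
    b <- cells[which(bad)[1], ]
    abort(sprintf(
      "cannot standardize cell (sex = %s, block = %s): %s.",
      b$sex, as.character(b$block),
      if (b$cell_n < 2) "fewer than 2 records" else "zero standard deviation"
    ))
  }
  records$fitness_z <- NULL
  records |>
    dplyr::left_join(cells, by = c("sex", "block")) |>
    dplyr::mutate(fitness_z = (.data$fitness - .data$cell_mean) / .data$cell_sd) |>
    dplyr::select(-"cell_n", -"cell_mean", -"cell_sd")
}

#' Flag candidate outliers on the standardized scale
#'
#' Flags records whose standardized fitness exceeds `k` in absolute value.
#' Flagging is deliberately separate from removal: records are never dropped
#' automatically, so that any exclusion is an explicit, recorded analyst
#' decision.
#'
#' @param records Standardized records (see [standardize_fitness()]).
#' @param k Absolute z-score threshold (default 3).
#'
#' @return The flagged rows as a tibble (possibly empty), in input order.
#'
#' @export
flag_outliers <- function(records, k = 3) {
  check_fitness_records(records, need_z = TRUE)
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("`k` must be a single positive number.")
  }
  tibble::as_tibble(records)[abs(records$fitness_z) > k, , drop = FALSE]
}

#' Per-line mean standardized fitness by sex
#'
#' Aggregates standardized records to one row per line, with the mean
#' standardized fitness of each sex pooled across blocks (standardization
#' has already removed block location and scale).
#'
#' @param records Standardized records covering both sexes for every line.
#'
#' @return A tibble with columns `line_id`, `mean_male_z`, `mean_female_z`,
#'   `n_male`, `n_female`, one row per line, ordered by `line_id`.
#'
#' @export
line_sex_means <- function(records) {
  check_fitness_records(records, need_z = TRUE)
  wide <- tibble::as_tibble(records) |>
    dplyr::group_by(.data$line_id, .data$sex) |>
    dplyr::summarise(
      mean_z = mean(.data$fitness_z), n = dplyr::n(), .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "sex",
      values_from = c("mean_z", "n"),
      names_glue = "{.value}_{ifelse(sex == 'M', 'male', 'female')}"
    )
  for (col in c("mean_z_male", "mean_z_female", "n_male", "n_female")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  incomplete <- wide$line_id[is.na(wide$mean_z_male) | is.na(wide$mean_z_female)]
  if (length(incomplete) > 0) {
    abort(paste0("line(s) missing one sex: ",
                 paste(incomplete, collapse = ", "), "."))
  }
  wide |>
    dplyr::select(
      "line_id",
      mean_male_z = "mean_z_male", mean_female_z = "mean_z_female",
      "n_male", "n_female"
    ) |>
    dplyr::arrange(.data$line_id)
}

#' Estimate the intersexual correlation for fitness from line data
#'
#' The full line-level estimate of \eqn{r_{mf}}: optionally drops the
#' records of excluded lines, re-standardizes the remaining raw fitness
#' values from scratch (so excluded lines no longer influence the cell means
#' and SDs), aggregates to per-line sex means, and correlates male against
#' female line means with [pearson_rmf()]. Re-standardization matters:
#' subsetting previously computed z-scores is not equivalent, because the
#' excluded lines would still have shaped the cell means and SDs.
#'
#' @param records Raw fitness records (a `fitness_z` column, if present, is
#'   recomputed).
#' @param exclude_lines Character vector of `line_id`s to drop before
#'   standardization (default none). At least 3 lines must remain.
#'
#' @return A one-row tibble as from [pearson_rmf()] (here `n` is the number
#'   of lines and `df = n - 2`), plus an `n_excluded` column.
#'
#' @export
estimate_rmf <- function(records, exclude_lines = NULL) {
  check_fitness_records(records)
  kept <- tibble::as_tibble(records)
  if (!is.null(exclude_lines) && length(exclude_lines) > 0) {
    kept <- dplyr::filter(kept, !.data$line_id %in% exclude_lines)
  }
  n_lines <- dplyr::n_distinct(kept$line_id)
  if (n_lines < 3) {
    abort(sprintf("need at least 3 lines after exclusion, got %d.", n_lines))
  }
  means <- kept |>
    standardize_fitness() |>
    line_sex_means()
  res <- pearson_rmf(means$mean_male_z, means$mean_female_z)
  res$n_excluded <- dplyr::n_distinct(records$line_id) - n_lines
  res
}

#' Sex-by-line interaction test (fixed-effects F)
#'
#' Fits an ordinary least-squares model of standardized fitness on sex,
#' line, and block (all categorical fixed effects) plus the sex-by-line
#' interaction, and tests the interaction with the residual-sum-of-squares
#' F comparison of the full model against the model without the interaction.
#' A significant interaction indicates sex-specific genetic (line) effects
#' on fitness — the crossing of line fitness ranks between the sexes. Block
#' is modelled as a fixed effect here; with few blocks this is a close,
#' simpler stand-in for a random-block mixed model.
#'
#' @param records Standardized records with at least 2 lines, both sexes,
#'   and at least 2 blocks; every sex-by-line combination must be observed.
#'
#' @return A one-row tibble with columns `F_stat`, `df1`, `df2`, `p_value`.
#'
#' @export
interaction_f_test <- function(records) {
  check_fitness_records(records, need_z = TRUE)
  d <- tibble::as_tibble(records) |>
    dplyr::mutate(
      sex = factor(.data$sex),
      line_id = factor(.data$line_id),
      block = factor(.data$block)
    )
  if (nlevels(d$line_id) < 2) abort("need at least 2 lines.")
  if (nlevels(d$sex) < 2) abort("need records from both sexes.")
  if (nlevels(d$block) < 2) abort("need at least 2 blocks.")
  cells <- tidyr::expand_grid(
    sex = levels(d$sex), line_id = levels(d$line_id)
  ) |>
    dplyr::anti_join(
      dplyr::distinct(d, sex = as.character(.data$sex),
                      line_id = as.character(.data$line_id)),
      by = c("sex", "line_id")
    )
  if (nrow(cells) > 0) {
    abort(paste0(
      "empty sex-by-line cell(s): ",
      paste(sprintf("(%s, %s)", cells$sex, cells$line_id), collapse = ", "), "."
    ))
  }
  full <- lm(fitness_z ~ sex + line_id + block + sex:line_id, data = d)
  reduced <- lm(fitness_z ~ sex + line_id + block, data = d)
  cmp <- anova(reduced, full)
  tibble::tibble(
    F_stat = cmp$F[2],
    df1 = as.integer(cmp$Df[2]),
    df2 = as.integer(cmp$Res.Df[2]),
    p_value = cmp$`Pr(>F)`[2]
  )
}

#' Report how suspect CI lines shift the intersexual correlation
#'
#' Bundles the diagnostics used to judge whether a few endosymbiont-free
#' (CI-affected) lines are driving an apparently negative intersexual
#' fitness correlation: the correlation with all lines, the correlation
#' after excluding the suspect lines (with re-standardization), the
#' slope-comparison t test between the two regressions, leave-one-line-out
#' correlations (each recomputed with re-standardization), and the per-line
#' fitness ranks by sex (rank 1 = highest mean standardized fitness).
#'
#' @param records Raw fitness records.
#' @param suspect_lines Character vector of `line_id`s suspected of CI; must
#'   be a subset of the lines present (may be empty).
#'
#' @return An object of class `ci_bias_report`: a list with elements
#'   `with_suspects` and `without_suspects` (one-row tibbles from
#'   [estimate_rmf()]), `slope_comparison` (from [compare_slopes()]),
#'   `leverage` (tibble `line_id`, `r_without`), `ranks` (tibble `line_id`,
#'   `rank_male`, `rank_female`), and `suspect_lines`. Supports [tidy()],
#'   [glance()], and [autoplot()].
#'
#' @export
ci_bias_report <- function(records, suspect_lines = character()) {
  check_fitness_records(records)
  records <- tibble::as_tibble(records)
  lines <- sort(unique(records$line_id))
  stray <- setdiff(suspect_lines, lines)
  if (length(stray) > 0) {
    abort(paste0("suspect line(s) not present in the data: ",
                 paste(stray, collapse = ", "), "."))
  }
  with_all <- estimate_rmf(records)
  without <- estimate_rmf(records, exclude_lines = suspect_lines)
  slope_cmp <- compare_slopes(
    b1 = with_all$slope, se1 = with_all$slope_se, n1 = with_all$n,
    b2 = without$slope, se2 = without$slope_se, n2 = without$n
  )
  leverage <- tibble::tibble(
    line_id = lines,
    r_without = purrr::map_dbl(
      lines, function(l) estimate_rmf(records, exclude_lines = l)$r
    )
  )
  means <- standardize_fitness(records) |> line_sex_means()
  ranks <- tibble::tibble(
    line_id = means$line_id,
    rank_male = dplyr::min_rank(dplyr::desc(means$mean_male_z)),
    rank_female = dplyr::min_rank(dplyr::desc(means$mean_female_z))
  )
  structure(
    list(
      with_suspects = with_all,
      without_suspects = without,
      slope_comparison = slope_cmp,
      leverage = leverage,
      ranks = ranks,
      line_means = means,
      suspect_lines = suspect_lines
    ),
    class = "ci_bias_report"
  )
}

#' @export
print.ci_bias_report <- function(x, ...) {
  cat("<ci_bias_report>\n")
  cat(sprintf(
    "  all %d lines:      r_mf = %+.3f (t = %+.3f, df = %d, p = %.3g)\n",
    x$with_suspects$n, x$with_suspects$r, x$with_suspects$t_stat,
    x$with_suspects$df, x$with_suspects$p_two_tailed
  ))
  cat(sprintf(
    "  excluding %d line(s): r_mf = %+.3f (t = %+.3f, df = %d, p = %.3g)\n",
    length(x$suspect_lines), x$without_suspects$r, x$without_suspects$t_stat,
    x$without_suspects$df, x$without_suspects$p_two_tailed
  ))
  cat(sprintf(
    "  slope comparison:  t = %+.3f, df = %d, p = %.3g\n",
    x$slope_comparison$t_stat, x$slope_comparison$df,
    x$slope_comparison$p_two_tailed
  ))
  invisible(x)
}

#' @rdname tidy.ci_bias_report
#' @method glance ci_bias_report
#' @export
glance.ci_bias_report <- function(x, ...) {
  tibble::tibble(
    n_lines = x$with_suspects$n,
    n_suspect = length(x$suspect_lines),
    r_with = x$with_suspects$r,
    p_with = x$with_suspects$p_two_tailed,
    r_without = x$without_suspects$r,
    p_without = x$without_suspects$p_two_tailed,
    slope_t = x$slope_comparison$t_stat,
    slope_df = x$slope_comparison$df,
    slope_p = x$slope_comparison$p_two_tailed
  )
}

#' Tidiers for CI bias reports
#'
#' `tidy()` returns the leave-one-line-out correlations joined with the
#' per-line sex-specific fitness ranks; `glance()` returns a one-row
#' summary with the correlations with and without the suspect lines and the
#' slope-comparison test.
#'
#' @param x A `ci_bias_report` from [ci_bias_report()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ci_bias_report
#' @export
tidy.ci_bias_report <- function(x, ...) {
  dplyr::left_join(x$leverage, x$ranks, by = "line_id") |>
    dplyr::mutate(suspect = .data$line_id %in% x$suspect_lines)
}
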