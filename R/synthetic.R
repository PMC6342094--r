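# Synthetic isofemale-line fitness data with tunable intersexual genetic
# correlation and optional CI-affected (uninfected) lines.

#' Design a synthetic isoline fitness experiment
#'
#' Describes the generative model for an isoline assay: per-line genetic
#' effects for the two sexes drawn from a bivariate normal with correlation
#' `rho_mf`, additive block effects, and residual noise, all on a common
#' latent scale. Female fitness is an offspring count
#' (`round(max(0, female_mean + female_scale * latent))`); male fitness is a
#' competitive paternity share, generated as the wild-type fraction of a
#' binomial paternity assay against tester males whose success probability
#' is `plogis(male_baseline_logit + latent)`.
#'
#' Lines listed in `ci_lines` are uninfected and suffer cytoplasmic
#' incompatibility: their females' expected offspring count collapses to
#' `ci_female_mean` and their males' latent log-odds of paternity gain
#' `ci_male_boost`. Setting `cured = TRUE` (see [cure()]) switches both
#' distortions off, emulating an assay repeated after clearing the
#' endosymbiont from all lines.
#'
#' @param n_lines Number of isolines (default 27).
#' @param n_blocks Number of assay blocks (default 3).
#' @param n_per_sex_per_block Individuals per sex per line per block
#'   (default 10).
#' @param rho_mf True intersexual genetic correlation of the line effects,
#'   in \[-1, 1\] (default 0).
#' @param sigma_line,sigma_block,sigma_resid Standard deviations of the
#'   line, block, and residual effects on the latent scale (defaults 0.5,
#'   0.25, 0.5).
#' @param female_mean Expected offspring count of an average female
#'   (default 60).
#' @param female_scale Offspring count per latent-scale unit (default 15).
#' @param male_baseline_logit Baseline log-odds that an offspring is sired
#'   by the focal male rather than one of the tester males (default
#'   `qlogis(0.2)`, an even chance against 4 testers).
#' @param n_offspring_assay Offspring scored per male paternity assay
#'   (default 100).
#' @param ci_lines Character vector of uninfected (CI-affected) line ids
#'   (default none).
#' @param ci_female_mean Expected offspring count of CI-affected females
#'   (default 5).
#' @param ci_male_boost Additive log-odds advantage of uninfected males
#'   (default 2).
#' @param cured If `TRUE`, generate the cured world: `ci_lines` keep their
#'   identities but no CI distortion is applied.
#'
#' @return An object of class `isoline_design` (a named list, with line ids
#'   `"L01"`, `"L02"`, ... in element `line_ids`).
#'
#' @examples
#' isoline_design(rho_mf = 0.5)
#' isoline_design(ci_lines = c("L07", "L12"))
#' @export
isoline_design <- function(n_lines = 27,
                           n_blocks = 3,
                           n_per_sex_per_block = 10,
                           rho_mf = 0,
                           sigma_line = 0.5,
                           sigma_block = 0.25,
                           sigma_resid = 0.5,
                           female_mean = 60,
                           female_scale = 15,
                           male_baseline_logit = qlogis(0.2),
                           n_offspring_assay = 100,
                           ci_lines = character(),
                           ci_female_mean = 5,
                           ci_male_boost = 2,
                           cured = FALSE) {
  design <- list(
    n_lines = as.integer(n_lines),
    n_blocks = as.integer(n_blocks),
    n_per_sex_per_block = as.integer(n_per_sex_per_block),
    rho_mf = rho_mf,
    sigma_line = sigma_line, sigma_block = sigma_block,
    sigma_resid = sigma_resid,
    female_mean = female_mean, female_scale = female_scale,
    male_baseline_logit = male_baseline_logit,
    n_offspring_assay = as.integer(n_offspring_assay),
    ci_lines = as.character(ci_lines),
    ci_female_mean = ci_female_mean,
    ci_male_boost = ci_male_boost,
    cured = isTRUE(cured)
  )
  design$line_ids <- sprintf("L%02d", seq_len(design$n_lines))
  class(design) <- "isoline_design"
  validate_isoline_design(design)
}

validate_isoline_design <- function(design) {
  if (!inherits(design, "isoline_design")) {
    abort("`design` must be created with isoline_design().")
  }
  chk <- function(cond, msg) if (!cond) abort(paste0("invalid design: ", msg))
  with(design, {
    chk(n_lines >= 1 && n_blocks >= 1 && n_per_sex_per_block >= 1 &&
          n_offspring_assay >= 1, "all counts must be >= 1.")
    chk(is.numeric(rho_mf) && abs(rho_mf) <= 1, "|rho_mf| must be <= 1.")
    chk(sigma_line >= 0 && sigma_block >= 0 && sigma_resid >= 0,
        "all SDs must be >= 0.")
    chk(all(ci_lines %in% line_ids),
        "ci_lines must be a subset of the design's line ids.")
  })
  design
}

#' @export
print.isoline_design <- function(x, ...) {
  cat("<isoline_design>\n")
  cat(sprintf(
    "  %d lines x %d blocks x %d per sex per block (%d records)\n",
    x$n_lines, x$n_blocks, x$n_per_sex_per_block,
    2L * x$n_lines * x$n_blocks * x$n_per_sex_per_block
  ))
  cat(sprintf(
    "  rho_mf = %g; SDs line %g, block %g, residual %g\n",
    x$rho_mf, x$sigma_line, x$sigma_block, x$sigma_resid
  ))
  if (length(x$ci_lines) > 0) {
    cat(sprintf(
      "  CI lines: %s%s\n", paste(x$ci_lines, collapse = ", "),
      if (x$cured) " (cured: no CI applied)" else ""
    ))
  }
  invisible(x)
}

#' Cure a design of its endosymbiont
#'
#' Returns the same design with `cured = TRUE`: the CI lines keep their
#' identities (and their line effects under a shared seed), but no female
#' fitness collapse or male boost is applied when generating data.
#' Idempotent.
#'
#' @param design An [isoline_design()].
#' @return The design with `cured = TRUE`.
#' @export
cure <- function(design) {
  validate_isoline_design(design)
  design$cured <- TRUE
  design
}

#' Generate individual-level isoline fitness records
#'
#' Draws a full synthetic dataset under the design's generative model. The
#' random draws are consumed in a fixed order that does not depend on
#' `ci_lines` or `cured` (male paternity counts are obtained by inverting
#' pre-drawn uniforms through the binomial quantile function), so datasets
#' generated from a design and its [cure()]d counterpart under the same seed
#' are identical except for the CI distortion itself — common random numbers
#' for low-variance paired comparisons.
#'
#' @param design An [isoline_design()].
#' @param seed Optional integer seed.
#'
#' @return A tibble of fitness records with columns `line_id`, `sex`
#'   (`"M"`/`"F"`), `block` (`"B1"`, ...), `individual`, `fitness` (females:
#'   nonnegative integer offspring count; males: paternity share in
#'   \[0, 1\]), and `infected` (logical line identity: `FALSE` for the
#'   `ci_lines`, whether or not the design is cured — curing removes the CI
#'   distortion, not the lines' identities).
#'
#' @examples
#' d <- isoline_design(n_lines = 5, ci_lines = "L02")
#' generate_isolines(d, seed = 1)
#' @export
generate_isolines <- function(design, seed = NULL) {
  validate_isoline_design(design)
  if (!is.null(seed)) set.seed(seed)
  L <- design$n_lines
  B <- design$n_blocks
  K <- design$n_per_sex_per_block
  n_per_sex <- L * B * K

  # fixed draw order, independent of CI settings
  z1 <- rnorm(L)
  z2 <- rnorm(L)
  g_male <- design$sigma_line * z1
  g_female <- design$sigma_line *
    (design$rho_mf * z1 + sqrt(1 - design$rho_mf^2) * z2)
  beta <- rnorm(B, 0, design$sigma_block)
  eps_f <- rnorm(n_per_sex, 0, design$sigma_resid)
  eps_m <- rnorm(n_per_sex, 0, design$sigma_resid)
  u_m <- runif(n_per_sex)

  idx <- tidyr::expand_grid(
    line = seq_len(L), block = seq_len(B), individual = seq_len(K)
  )
  ci <- design$line_ids[idx$line] %in% design$ci_lines
  apply_ci <- ci & !design$cured

  f_mean <- ifelse(apply_ci, design$ci_female_mean, design$female_mean)
  latent_f <- g_female[idx$line] + beta[idx$block] + eps_f
  fitness_f <- round(pmax(0, f_mean + design$female_scale * latent_f))

  latent_m <- design$male_baseline_logit + g_male[idx$line] +
    beta[idx$block] + eps_m + ifelse(apply_ci, design$ci_male_boost, 0)
  wt <- qbinom(u_m, design$n_offspring_assay, plogis(latent_m))
  fitness_m <- wt / design$n_offspring_assay

  one_sex <- function(sex, fitness) {
    tibble::tibble(
      line_id = design$line_ids[idx$line],
      sex = sex,
      block = sprintf("B%d", idx$block),
      individual = sprintf("%s_%s_B%d_%02d", design$line_ids[idx$line],
                           sex, idx$block, idx$individual),
      fitness = fitness,
      infected = !ci
    )
  }
  dplyr::bind_rows(one_sex("F", fitness_f), one_sex("M", fitness_m)) |>
    dplyr::arrange(.data$line_id, .data$block, .data$sex, .data$individual)
}
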