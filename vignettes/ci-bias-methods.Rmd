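---
title: "How cytoplasmic incompatibility can mimic intralocus sexual conflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How cytoplasmic incompatibility can mimic intralocus sexual conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciconflict)
library(dplyr)
```

## The problem

Intralocus sexual conflict is commonly diagnosed from the intersexual
genetic correlation for fitness, $r_{mf}$: the Pearson correlation between
male and female genetic (line-level) fitness values. Strongly negative
$r_{mf}$ is read as evidence that alleles good for one sex are bad for the
other.

Unidirectional cytoplasmic incompatibility (CI), caused by maternally
transmitted endosymbionts such as *Wolbachia*, can forge this signature
without any sexually antagonistic allele. In a population where most
genotypes are infected, females of an *uninfected* genotype produce few or
no offspring when mated to infected males, while uninfected males lose
nothing — and are often *better* sexual competitors than infected males.
Uninfected genotypes therefore combine very low female fitness with high
male fitness: exactly the pattern a negative $r_{mf}$ summarizes.

`ciconflict` provides (i) a Monte-Carlo simulator quantifying how easily CI
produces significant negative $r_{mf}$ estimates, (ii) the statistics used
in such analyses, (iii) an isofemale-line analysis pipeline, and (iv) a
synthetic isoline data generator so the whole pipeline is testable
end-to-end without external data.

## The scenario simulator

Each replicate draws one mean fitness value per sex for each of
`n_genotypes` (default 10) genotypes:

* infected genotypes: male and female fitness independently
  $\mathcal{N}(60, 15^2)$;
* uninfected genotypes (a fraction `ci_fraction`, rounded to a whole number
  of genotypes, chosen uniformly at random each replicate): female fitness
  $\mathcal{N}(5, 2^2)$ (CI collapse), male fitness either baseline
  (`male_mode = "random"`) or $\mathcal{N}(85, 15^2)$
  (`male_mode = "high"`).

Draws are plain normal deviates — not truncated at zero, so a CI female can
(rarely, about 0.6% of draws from $\mathcal{N}(5,2^2)$) receive a negative
value. Keeping the raw normal model makes the simulator exactly the
idealized thought experiment it is meant to be; the *isoline generator*
below is the place where measurement-scale realism lives.

Per replicate, `run_scenario()` computes the Pearson correlation between
the 10 male and 10 female values ($t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-tailed
$p$ on $n-2$ df) and tallies signs and significance at $\alpha = 0.05$. A
correlation of exactly 0 (a measure-zero event) would count as positive;
a zero-variance replicate is recorded as undefined, excluded from the
tallies, and flagged with a warning. `simulate_table1()` sweeps the
$\{0, 10, 20\%\ \mathrm{CI}\} \times \{\text{random, high}\}$ grid with 100
replicates per scenario:

```{r table1}
simulate_table1(scenario_config(), seed = 1)
```

With no CI, about half the correlations are negative and about 5 in 100 are
significant — the nominal false-positive rate. With 10–20% CI *and* fitter
uninfected males, most correlations turn negative and a substantial number
become significantly negative, none significantly positive.

**Randomness.** Each battery is reproducible given `(config, seed)`:
replicates are drawn sequentially from one seeded stream. We deliberately
did not implement per-replicate substreams (base R has no cheap
stream-jumping); the cost is only that replicate $k$ of a battery cannot be
regenerated without replaying the first $k-1$.

## The statistics

* `pearson_rmf()` — product-moment $r$, its $t$ and two-tailed $p$, and the
  OLS slope (female on male) with its standard error. For simple
  regression the slope's $t$ equals the correlation's $t$, so one test
  serves both descriptions.
* `compare_slopes()` — $t = (b_1 - b_2)/\sqrt{s_{b_1}^2 + s_{b_2}^2}$ on
  $n_1 + n_2 - 4$ df (two slopes and two intercepts estimated): the
  classical test for comparing two independent regression slopes, e.g. the
  line-mean regression with and without suspect CI lines (27 and 25 lines
  give df = 48).
* `chi_square_independence()` — Pearson $\sum (O-E)^2/E$ with margins-based
  expectations, no continuity correction (tallies across scenarios are
  counts large enough that Yates' correction would only blur the
  comparison).
* `binomial_sign_test()` — for a split such as 18 significant-negative
  versus 0 significant-positive correlations: the textbook
  $z = (k - np_0)/\sqrt{np_0(1-p_0)}$ without continuity correction,
  plus the exact two-sided $p$ (sum of binomial point masses no larger
  than the observed one).

## The isoline pipeline

Empirical isofemale-line assays measure, say, 10 individuals per sex per
line per block, female fitness as a 7-day offspring count and male fitness
as a competitive paternity share. The pipeline mirrors the standard
analysis:

1. `standardize_fitness()` — Z-transform within each sex-by-block cell
   (sample SD, $n-1$), putting offspring counts and paternity shares on one
   scale and absorbing block location/scale.
2. `flag_outliers()` — flag $|z| > k$ (default $k = 3$); removal is never
   automatic. Published analyses often mention removing "an outlier"
   without stating a criterion, so the package makes the criterion explicit
   and the removal a logged user decision.
3. `line_sex_means()` — mean $z$ per line and sex, pooled across blocks.
   Pooling (rather than per-block means first) is the natural choice once
   standardization has removed block effects; with a balanced design the
   two are identical.
4. `estimate_rmf()` — correlate male against female line means. With
   `exclude_lines`, the excluded lines' records are dropped and the data
   **re-standardized from scratch** before aggregation: excluded lines must
   stop influencing the cell means and SDs. Subsetting old z-scores is not
   equivalent, and the test suite pins this distinction.
5. `interaction_f_test()` — OLS fit of
   `fitness_z ~ sex + line + block + sex:line` with the RSS F-test of the
   interaction. A significant sex-by-line interaction means line effects
   differ between the sexes (crossing fitness ranks). Block is a *fixed*
   effect here, a deliberate simplification of the random-block mixed model
   used in some empirical analyses: with ~3 blocks, block variance is
   barely estimable as a random effect, and the fixed-effect F-test has
   close to nominal size (the acceptance suite verifies type-I error in
   [0.03, 0.07] at $\alpha = 0.05$ over 500 null simulations). Degrees of
   freedom are reported honestly from the OLS fit.
6. `ci_bias_report()` — the exclusion analysis in one object: $r_{mf}$ with
   and without suspect lines, the slope comparison between the two
   regressions, leave-one-line-out correlations, and per-line sex-specific
   fitness ranks. `autoplot()` shows the line-mean scatter with both fits.

## The synthetic isoline generator

`isoline_design()` + `generate_isolines()` emulate the assay: default 27
lines × 3 blocks × 10 individuals per sex per block. On a common latent
scale, line effects $(g_{l,m}, g_{l,f})$ are bivariate normal with SD
`sigma_line` and correlation `rho_mf` (the *true* intersexual genetic
correlation — the parameter the pipeline should recover), block effects
have SD `sigma_block`, residuals SD `sigma_resid`.

* Female record: `round(max(0, female_mean + female_scale * latent))` — a
  nonnegative integer offspring count. Unlike the scenario simulator, the
  generator respects the measurement scale of a real assay; the two modules
  intentionally differ here.
* Male record: `wt / n_offspring_assay`, with
  `wt ~ Binomial(n_offspring_assay, plogis(male_baseline_logit + latent))` —
  the wild-type paternity share scored against tester males. We use the
  share rather than a wild-type:tester *ratio* to avoid division by zero
  when the focal male sires everything.
* CI lines (`ci_lines`): female expectation collapses to `ci_female_mean`;
  males gain `ci_male_boost` on the log-odds scale. `cure()` switches both
  distortions off while keeping line identities, emulating re-assaying the
  same lines after antibiotic curing.

Defaults: `sigma_line = 0.5`, `sigma_block = 0.25`, `sigma_resid = 0.5`,
`female_mean = 60`, `female_scale = 15` (so female records have mean ≈ 60
and SD ≈ 11, matching the scale of the scenario simulator),
`male_baseline_logit = qlogis(0.2)` (an even chance against 4 testers),
`n_offspring_assay = 100`, `ci_female_mean = 5`, `ci_male_boost = 2`
(paternity odds ≈ 0.65 for uninfected males). No empirical
variance-component estimates exist for this assay, so the latent SDs were
fixed once at values giving roughly half the individual-level variance to
line identity after block removal — a heritable but noisy fitness measure —
and are tunable, not asserted.

The generator uses **common random numbers**: all stochastic draws are made
in an order that does not depend on `ci_lines` or `cured` (binomial counts
come from inverting pre-drawn uniforms), so a design and its cured twin
generated with the same seed differ *only* through the CI distortion. This
makes paired cured/uncured contrasts low-variance.

What the generator does not emulate: mate choice, partial CI penetrance,
infection-frequency dynamics, larval competition, or overdispersed
fecundity. Passing tests therefore show the pipeline's statistical
behaviour under a clean additive-genetic world with CI, not that real fly
data satisfy these assumptions.

```{r bias-demo}
design <- isoline_design(rho_mf = 0, ci_lines = c("L07", "L12"))
raw <- generate_isolines(design, seed = 1)
report <- ci_bias_report(raw, suspect_lines = c("L07", "L12"))
report
glance(report)
```

With a true $\rho = 0$, two CI lines out of 27 push the estimated $r_{mf}$
strongly negative; excluding them (or generating the cured world) restores
an estimate near zero. Over many seeds the mean estimate with CI lines is
significantly negative while the excluded and cured means are near 0 — the
bias the package exists to demonstrate. At the defaults the simulated
female collapse (60 → 5 offspring) is deliberately severe, an essentially
complete CI; real assays with partial penetrance would sit between the
cured and uncured extremes.

## Numerical and design notes

* $|r|$ is clamped into $[-1, 1]$ against floating-point overshoot;
  $r = \pm 1$ yields $t = \pm\infty$, $p = 0$.
* `compare_slopes()` with both SEs zero: $t = 0$ if the slopes are equal,
  otherwise signed infinity with a warning.
* Zero-variance inputs are errors in `pearson_rmf()` (the user called it on
  degenerate data) but are converted to excluded-with-warning undefined
  results inside scenario batteries (a battery should not crash on one
  degenerate replicate).
* Tests and the acceptance checks run at desk scale: 50 seed batteries of
  100 replicates per scenario, 200 generator seeds for parameter recovery
  and bias reproduction, 500 null simulations for the interaction test's
  size. These sizes give Monte-Carlo standard errors comfortably inside the
  tolerances tested.

## Limitations

* The interaction test is a fixed-block OLS approximation; with many blocks
  or strong block-by-line structure a mixed model (e.g. lme4) should be
  preferred.
* The exact contingency tables some analyses report alongside scenario
  grids depend on unstated table constructions; the package provides the
  generic chi-square test rather than guessing a construction.
* $r_{mf}$ from isoline means is attenuated by residual noise in the line
  means (about 3–5% at the default design), which is well inside the
  tolerance of the parameter-recovery checks but matters for very small
  assays.
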