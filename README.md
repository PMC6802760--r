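# visualspan

Tools for analysing **visual span** experiments — studies that measure how
many adjacent characters a reader can recognize reliably in a single
fixation, and how that limit depends on factors such as adult age and the
pattern complexity of the script (e.g. stroke-dense Chinese characters).
The package is aimed at vision and reading researchers who run the
**trigram task**: three-character strings flashed briefly at varying
horizontal eccentricities around a fixation point, with full report of all
three characters.

## What it computes

Starting from trial-level records (participant, age group, complexity
level, trigram center, per-character correctness), the pipeline:

1. **Scores** each character at the display position it occupied
   (`score_trial()`, `score_trials()`): a trigram centered at −3 places its
   characters at −4, −3, −2; positions outside −7 … +7 are shown but not
   scored.
2. **Builds span profiles** (`build_profiles()`): percent correct at each
   of the 15 scored positions, per participant × complexity (27
   observations per position under the default balanced 459-trial
   session).
3. **Fits profile curves** (`fit_gaussian()`): a single Gaussian
   `A·exp(−(x−μ)²/2σ²)` and a sum of two Gaussians, by bounded
   Levenberg–Marquardt least squares, with a deterministic selection rule
   (`select_best_fit()`) replacing by-eye model choice.
4. **Extracts the span** (`compute_span()`): the width of the fitted curve
   at an 80%-correct criterion, with left/right extents from fixation and
   their rightward asymmetry; a curve never reaching the criterion records
   a span of zero. The span is also expressed in **bits of information
   transmitted** (`info_transmitted()`, `span_bits()`), from 0 bits at
   chance (3.8% for a 26-character set) to log₂26 ≈ 4.7 bits per position
   at ceiling.
5. **Runs the group statistics** (`mixed_anova()`,
   `pairwise_age_by_complexity()`, `pearson_r()`): 2 (age) × 3
   (complexity) split-plot ANOVA with Greenhouse–Geisser correction and
   partial η², Bonferroni-corrected between-group t-tests with Cohen's d,
   and Pearson correlations between span size and sentence reading speed
   (`compute_reading_speed()`, characters per minute).

A seeded synthetic cohort generator (`generator_config()`,
`simulate_cohort()`) produces trial-level and reading data with the
structure the analysis assumes — eccentricity-dependent accuracy with
rightward asymmetry, a complexity- and age-dependent crowding penalty on
the doubly-flanked middle character, uniform guessing over the character
set, and reading speeds linear in span — so every stage is testable
without access to raw participant data. Closed-form "true" spans of the
latent model (`true_span()`) serve as recovery targets.

## Worked example

```r
library(visualspan)

cohort   <- simulate_cohort(generator_config(seed = 2026))  # 21 per group
profiles <- build_profiles(cohort$trials, default_design())
spans    <- estimate_spans(profiles)

round(tapply(spans$span_chars, list(spans$age_group, spans$complexity), mean), 1)
#>       high low medium
#> older  3.1 7.4    6.3
#> young  5.6 7.1    6.4

mixed_anova(spans, gg_correct = TRUE)
#> Mixed-design ANOVA on `span_chars` (Greenhouse-Geisser corrected)
#>                effect df_num df_den     F        p partial_eta_sq gg_epsilon
#>             age_group   1.00  40.00 16.31 2.37e-04          0.290         NA
#>            complexity   1.89  75.59 81.36 4.89e-19          0.670      0.945
#>  age_group:complexity   1.89  75.59 20.95 1.02e-07          0.344      0.945

pairwise_age_by_complexity(spans)
#>  complexity      contrast     t df        p    p_adj cohens_d
#>         low young - older -0.81 40 4.24e-01 1.00e+00    -0.25
#>      medium young - older  0.48 40 6.36e-01 1.00e+00     0.15
#>        high young - older  6.46 40 1.08e-07 3.24e-07     1.99

speeds <- compute_reading_speed(cohort$reading)
hi <- span_speed_join(spans, speeds, "per_complexity", complexity = "high")
pearson_r(hi$span, hi$cpm)
#> Pearson r = 0.475 (n = 42, t(40) = 3.41, p = 0.001491)
```

Read: spans shrink with pattern complexity for both groups, the age
deficit is confined to high complexity (≈3.1 vs ≈5.6 characters; d ≈ 2),
the within-subject effects carry a GG ε of 0.95, and individual span size
predicts reading speed most strongly for high-complexity stimuli. Mean
rightward asymmetry here is +0.27 (older) and +0.61 (young) characters.

`run_simulate()` / `run_analyze()` wrap the pipeline into file-based
stages (trials/reading CSV in, profiles/spans CSV + stats JSON + text
report out); `inst/scripts/visualspan.R` exposes them as `simulate` /
`analyze` / `report` subcommands for shell use.

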