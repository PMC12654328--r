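# flychoice

Individual-level analysis of phototactic choice in parallel single-fly
T-maze (FlyVac-style) assays.

## The problem

In a FlyVac rig, each fly is startled and then repeatedly chooses between
an illuminated and a dark arm of a T-maze, typically 40 trials per fly.
Two questions arise for a treatment comparison (for example, larval
serotonergic manipulation with aMW, 5-HTP or an SSRI against a control
diet):

1. **Location** — does the treatment shift the mean choice bias? Each fly
   yields a *light-choice probability* (LCP, the proportion of toward-light
   choices, in [0, 1]) and an equivalent *phototaxis index*
   (mean of the ±1 trial scores, = 2·LCP − 1, in [−1, 1]).
2. **Dispersion** — does the treatment change *between-fly variability*,
   i.e. how strongly individuals differ from one another? Dispersion within
   a group is quantified by the scaled median absolute deviation of the
   per-fly phototaxis indices, MADₙ = 1.4826 × MAD, which estimates the SD
   under normality while being robust to heavy tails.

Because per-fly summaries of 40 binary trials are heavily tied and
non-normal, all confirmatory inference is nonparametric, with the
individual fly as the unit of inference:

- **Location:** permutation Kruskal–Wallis (tie-corrected H on ranks,
  group labels permuted across flies with group sizes preserved), then
  pairwise permutation tests on group mean differences, Holm step-down
  corrected.
- **Dispersion:** a global permutation test with the *range* of group MADₙ
  as its statistic, pairwise |ΔMADₙ| permutation tests with Holm
  correction, and BCa (bias-corrected and accelerated) bootstrap 95% CIs
  for each group's MADₙ.
- **Descriptive only:** pooled-trial proportions with Wilson 95% CIs, a
  groups × {toward, away} chi-square, and pairwise two-proportion z-tests
  with MOVER-W difference intervals (these treat trials as independent and
  are flagged descriptive in every report).
- **Robustness screens:** a pre-specified 3-MAD extreme-value screen on
  per-fly LCP and lane/side balance diagnostics.

A beta-binomial synthetic-cohort generator (per-fly latent choice
probability `p_i ~ Beta` with mean μ and intraclass correlation ρ, so that
`Var(LCP) = μ(1−μ)[ρ + (1−ρ)/m]` over m trials) makes every stage testable
without any experimental data, and supports calibration and power studies.

## Worked example

```r
library(flychoice)

cfg <- analysis_config(synthetic_spec = flyvac_cohort_spec(1),
                       B_perm = 10000, B_boot = 10000, seed = 1)
report <- run_analysis(cfg)
print(report)
#> Phototactic-choice analysis report
#>   source: synthetic cohort (seed 1, B_perm 10000, B_boot 10000, proportion_ge)
#>   cohort: 1224 retained / 41 excluded
#>   location: KW H = 295.15, p = 0
#>   dispersion: MADn range = 0.0741, p = 0.7332
#>   outliers flagged: 58

report$dispersion$summary
#>    group_label n_flies  mad    madn            scale bca_lower bca_upper
#> 1      Control     299 0.20 0.29652 phototaxis_index   0.22239  0.296520
#> 2          aMW     310 0.20 0.29652 phototaxis_index   0.22239  0.296520
#> 3        5-HTP     296 0.20 0.29652 phototaxis_index   0.22239  0.333585
#> 4 Escitalopram     319 0.25 0.37065 phototaxis_index   0.29652  0.444780
```

Reading the output: 1265 synthetic flies were generated in four diet
groups; 41 incomplete flies were excluded by the 40-trial completion
filter. Per-fly LCP differs strongly between groups (H = 295.2 on 3 df
equivalent ranks; none of 10,000 label permutations reached the observed
H, so the permutation p-value is reported as 0, i.e. < 1/10,000). The
SSRI-like group is the most variable (MADₙ 0.371 vs 0.297), an observed
MADₙ range of 0.074; on this synthetic cohort the global dispersion
permutation test does not reject (p = 0.73) because group MADₙ values move
on a coarse grid (see the methods vignette for why this statistic is
conservative at 40 trials/fly). The signed pairwise tables live in
`report$location$pairwise`, `report$dispersion$pairwise` and
`report$pooled$contrasts` (six rows each for four groups).

A command-line wrapper with `simulate` and `analyze` subcommands is
installed at `inst/scripts/flychoice`.

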