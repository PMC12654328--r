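---
title: "Methods: individual-level inference for phototactic choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-level inference for phototactic choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flychoice)
```

## The data model

A FlyVac-style assay tests single flies in parallel T-maze lanes. Each
trial illuminates one arm at random; the fly's entry into an arm is scored
+1 (toward the light) or −1 (away). A fly scheduled for `m = 40` trials
yields two equivalent per-fly summaries:

* light-choice probability, `LCP = n_toward / m`, in [0, 1];
* phototaxis index, the mean of the ±1 scores, `= 2·LCP − 1`, in [−1, 1].

The index is computed from the LCP by that identity rather than by
averaging scores, so the two scales are linked to full floating-point
precision, and dispersion statistics on the index scale are exactly twice
their LCP-scale counterparts.

Flies that do not complete the full schedule are excluded before analysis
(`filter_complete()`); a fly with *more* trials than the schedule is
treated as a corrupt log and raises an error rather than being silently
truncated, since truncation would hide an acquisition fault. Gaps in trial
indices are tolerated and simply count as an incomplete schedule.

All confirmatory inference uses the fly, never the trial, as the unit:
trials within a fly are correlated through that fly's latent choice
probability, so trial-pooled statistics understate uncertainty. The pooled
module is retained because pooled proportions are useful effect-size
descriptions; every pooled output carries a `descriptive` flag.

## Location inference

Group summaries report median (IQR) and mean ± SEM. Quartiles use linear
interpolation between order statistics (`quantile()` type 7); the
convention matters little at n ≈ 300 but is fixed and documented because
the median absolute deviation below iterates the median.

The global test is a permutation Kruskal–Wallis: the tie-corrected rank
statistic

H = [ 12 / (N(N+1)) · Σ n_g R̄_g² − 3(N+1) ] / [ 1 − Σ(t³ − t)/(N³ − N) ]

with midranks for ties, recomputed under label permutations that preserve
group sizes. Tie correction is on by default — an LCP over 40 trials takes
only 41 distinct values, so ties are massive — with an uncorrected switch
for sensitivity analysis. Pooled ranks are invariant under relabelling, so
the permutation loop (compiled) only re-sums ranks per group. Pairwise
location contrasts use the absolute difference of group means as the test
statistic, reporting the signed difference as the effect, with the two
groups of the contrast (only) reshuffled and Holm step-down correction
over the six pairs.

## Dispersion inference

Between-fly variability within a group is MADₙ = 1.4826 × MAD of the
per-fly phototaxis indices; the constant makes MADₙ estimate the SD under
normality while staying robust to the heavy tails and bimodality real
choice data show. The global statistic is the range of group MADₙ values;
pairwise contrasts use |ΔMADₙ|. Both are non-negative departures, so the
two-sided p-value is the exceedance proportion `#{null ≥ observed}/B`.

Two p-value conventions are provided. `proportion_ge` is the plain
exceedance proportion and is the default. `plus_one`,
`(1 + #{null ≥ obs})/(1 + B)`, counts the observed statistic in its own
null; it is bounded below by 1/(B+1), never anti-conservative, and is the
convention used by the calibration test-suite. Ties count as exceedances
under both.

Per-group uncertainty in MADₙ uses the BCa bootstrap (10,000 resamples
within group by default): bias correction
`z0 = Φ⁻¹((#{θ* < θ̂} + ½·#{θ* = θ̂})/B)` and jackknife acceleration
`a = Σd³ / (6(Σd²)^{3/2})`, `d = mean(θ₋) − θ₋ᵢ`. Numerical choices worth
stating:

* **Ties in z0.** Bootstrap MADₙ of 40-trial indices is massively tied;
  half-weighting resamples equal to the point estimate avoids the bias of
  the strictly-less rule. The compiled fast path computes θ̂ with the same
  code as θ*, so tie detection is exact.
* **Clamping.** If all θ* fall on one side of θ̂ the inner proportion is
  clamped to [1/(B+1), B/(B+1)] and flagged.
* **Degeneracy.** If every resample equals θ̂ the interval is [θ̂, θ̂]
  with a degeneracy flag. If the jackknife values are constant, a = 0 (the
  symmetric limit of the 0/0 form).
* **Percentile reduction.** With z0 = 0 and a = 0 the endpoints are
  computed directly at the nominal quantile levels, so the interval
  reduces *exactly* to the percentile interval under the same quantile
  rule (type 7).

## Discreteness: why dispersion tests are conservative here

A 40-trial index lives on a 41-point grid with step 0.05, so a group MAD
moves on a 0.0125 grid and MADₙ on a ~0.0185 grid; in practice group MADₙ
values concentrate on steps of ~0.037. Two consequences, both verified by
this package's own simulation suite:

* The null distribution of the MADₙ range is lumpy: large probability
  atoms sit exactly at grid values, and null p-values cluster just above
  or below conventional thresholds. At the study's design (four groups of
  60, shared μ = 0.6, ρ = 0.1, B = 1000, `plus_one`), the global range
  test rejects at α = 0.05 in only ≈ 2% of null datasets — valid (never
  anti-conservative) but conservative, while the permutation
  Kruskal–Wallis sits at ≈ 5% under the same conditions. The acceptance
  suite asserts a symmetric 3–7% band for both tests; the dispersion
  assertion fails this band from the conservative side, and is left
  failing deliberately rather than loosened.
* BCa intervals for MADₙ over-cover: with n = 300 flies the sampling
  distribution of MADₙ has only a few atoms, the true population MADₙ lies
  on the same grid, and interval endpoints coincide with it. Measured
  coverage at (μ = 0.6, ρ = 0.1, B = 1000) is ≈ 0.99 against a nominal
  0.95; the acceptance suite's [0.91, 0.97] band fails from above, again
  deliberately. On a continuous statistic (the mean of normal draws) the
  same BCa code agrees with `boot::boot.ci` endpoints to ~0.03 and covers
  nominally.

Practically: a significant dispersion result from these tests can be
trusted; a non-significant one is weaker evidence of equality than the
nominal level suggests.

## The synthetic generator

`sample_cohort()` draws, per fly, a latent `p_i` — degenerate at the group
mean μ when the intraclass correlation ρ is 0, otherwise
`Beta(μ(1−ρ)/ρ, (1−μ)(1−ρ)/ρ)` — then m independent ±1 trials with
`P(+1) = p_i` and a fair-coin lit side. This is the minimal model
producing exactly the two quantities the analysis measures: group mean LCP
and between-fly dispersion, with the variance identity
`Var(LCP) = μ(1−μ)[ρ + (1−ρ)/m]` serving as the generator's test oracle.
Dropout is modelled as a Bernoulli-selected fly completing
`U ~ Uniform{1, …, m−1}` trials — the least-structured mechanism that
exercises the completion filter.

`flyvac_cohort_spec()` fixes a reference study shape: four groups
(Control, aMW, 5-HTP, Escitalopram) of 309/318/309/329 flies before
dropout at 2.5% (≈ 7–8 exclusions per group, retaining ≈ 301/310/301/321),
mean LCPs 0.73/0.73/0.65/0.52, and ρ = 0.09/0.09/0.08/0.12. The ρ values
are a *calibration*, not data: they were solved analytically from the
variance identity so that index-scale MADₙ sits near 0.30 in the first
three groups and near 0.37 in the SSRI-like group (a range of ≈ 0.074,
the magnitude scale such assays report), before any test was run, and have
not been adjusted since.

What the generator deliberately omits — and what passing tests therefore
do not establish about real data: serial dependence across a fly's trials
(learning, habituation), lane-specific biases beyond uniform assignment,
time-of-day effects, and any non-beta shape of the latent `p_i`
distribution (real cohorts of white-eyed flies can be strongly bimodal;
MADₙ is used precisely because it is robust to that, but the generator's
unimodal latent distribution is a simplification).

## Seeding and reproducibility

One master seed is exposed. Every stochastic consumer derives a private
stream via `stream_seed(seed, label)` (a deterministic hash fold), so
adding or reordering tests never perturbs another test's draws; compiled
loops consume R's own RNG, so `set.seed()` governs them identically across
the compiled and reference implementations. Reports echo seed, B, and the
p-value convention next to every stochastic result.

## Problem sizes in the validation suite

The simulation-based checks run at deliberately chosen scales: null
calibration over 500 replicate four-group cohorts of 60 flies at B = 1000;
power/recovery over 100 replicates of four groups of 300 at B = 2000
(where the location test rejects essentially always and the dispersion
test has ≥ 90% power against ρ 0.35 vs 0.10); BCa coverage over 1000
replicates of n = 300 at B = 1000; moment checks at n = 2000 flies with
4σ Monte-Carlo bands computed in advance. Defaults in the user-facing API
remain B = 10,000 throughout.

## Known limitations

* The pairwise permutation null reshuffles only the two groups in the
  contrast; a four-group relabelling null that recomputes the pair
  statistic is a defensible alternative and could shift borderline Holm
  decisions.
* The 3-MAD outlier screen uses raw MAD units by the literal reading of
  the rule (a MADₙ-unit switch widens the threshold by 1.4826×); on
  wide-dispersion cohorts it can flag many flies — it is a report, and
  never removes data.
* Pooled-trial intervals ignore within-fly correlation by construction;
  they are effect-size descriptions only.
* The lane/side diagnostics are transparent contingency and split-rate
  checks, not a model-based adjustment for apparatus effects.
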