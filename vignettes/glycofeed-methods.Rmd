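---
title: "Methods: fed-batch kinetics, compositional glycan statistics, and the study simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fed-batch kinetics, compositional glycan statistics, and the study simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and numerical choices behind
`glycofeed`: what each stage computes, the assumptions it makes, the
tunable parameters with their units and defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the methodology was genuinely open.

## 1. Cell-specific rates from daily time courses

Fed-batch cultures are sampled once per day, pre-feed. All rate estimators
work on these discrete samples:

* **Specific growth rate** `mu_i = (ln VCD_i - ln VCD_{i-1}) / (t_i - t_{i-1})`
  (1/d). Intervals containing nonpositive or missing VCD are flagged `NA`
  rather than raising an error, so a single bad reading does not abort a
  batch analysis.
* **Integral viable cell density** uses the trapezoid rule,
  `IVCD_i = (VCD_{i-1} + VCD_i)(t_i - t_{i-1})/2` (1e6 cells·d/mL), with the
  running sum anchored at 0 on the first sampling day. The trapezoid is
  exact for VCD affine in time (tested to 1e-12 relative).
* **Lactate rate** `q_LAC = dLAC/dIVCD` on nominal 48-h intervals and
  **productivity** `q_P = dP/dIVCD` on 24-h intervals, with units fixed by
  1 mM = 1e6 pmol/mL and 1 mg/L = 1e6 pg/mL. Positive `q_LAC` is
  production, negative is consumption. Negative `q_P` is permitted: feeding
  dilutes the product pool and the estimator reports what was measured. No
  dilution correction is applied to measured concentrations; dilution is
  modeled only inside the simulator. When a sampling day is missing, the
  interval widens to the nearest available measurements and carries a
  `widened` flag rather than silently dropping data.
* **Glucose consumption** is estimated per feeding window by ordinary least
  squares of glucose concentration on cumulative IVCD,
  `c_GLC = slope * IVCD_sum + d + eps`; the reported rate is `-slope`
  (consumption positive), both on the native scale (g/L per 1e6 cells·d/mL)
  and converted to pg/cell/d (x1000). Windows are half-open
  `[feed_k, feed_{k+1})`: the pre-feed sample drawn on the day of
  `feed_{k+1}` still reflects consumption during window `k` and belongs to
  it. Because samples are pre-feed, a window of a daily-fed strategy
  contains a single measurement; by default the known post-feed
  replenishment concentration (the feed's glucose target) is added as a
  synthetic point at the feed day (`use_postfeed = TRUE`), giving every
  window at least two points. Windows still shorter than two points are
  skipped with a warning. Fits are per replicate; strategy-level summaries
  are taken downstream. Residuals are retained for diagnostics.

All estimators are invariant to a constant shift of the time axis.

## 2. Glycoform nomenclature and indices

An intact IgG carries one N-glycan per heavy chain; the pair is written
`"X ⋅ Y"` with tokens `G0/G1/G2` (0/1/2 terminal galactoses), a trailing
`F` for core fucose, and `none` for an unoccupied site. Parsing derives
`g_j` (total galactoses) and `d_j` (possible galactosylation sites). A
present glycan contributes two sites; an absent arm contributes zero —
sites cannot exist without a glycan, so `"none ⋅ G0F"` has `d_j = 2`, not
4. Arms are stored in a deterministic canonical order (present first, then
ascending galactose count, afucosylated before fucosylated, then token
text), so `"G1F ⋅ G0F"` and `"G0F ⋅ G1F"` are one species. ASCII `"."` is
accepted as separator on input; rendered labels always use `"⋅"`.

Abundance tables are fractional (percent; each sample sums to 100 after
normalization, to 1e-9). Input rows deviating from 100 by up to 0.5
percentage points are renormalized with a warning; larger deviations are
treated as corrupt files and rejected.

The **galactosylation index** is the abundance-weighted site occupancy
`100 * sum_j(A_j g_j) / sum_j(A_j d_j)`; the **glycation index** is the
analogous occupancy of a fixed maximum of three backbone hexose sites on
the deglycosylated antibody, `100 * sum_i(g_i f_i) / sum_i(s_i f_i)` with
`s_i = 3`. Both are bounded in [0, 100] and linear in pooled samples.

### Hexosylation-bias correction

On the intact protein, a backbone glucose adduct (glycation) and a terminal
galactose are isobaric (+162 Da), so the intact-level hexose ladder mixes
the two. The correction assumes glycation acts independently of glycan
composition: the observed hexose-count distribution within each backbone
class (presence/fucosylation pattern) is the true galactosylation ladder
convolved with the sample's glycation distribution. The implementation
deconvolves each (sample, class) ladder by non-negative least squares
against the banded convolution matrix built from the measured glycation
distribution, redistributes corrected mass over the class's adduct-free
species proportionally to their observed abundances at each galactose
count, clips at zero, and renormalizes the sample to 100. When no clipping
occurs the correction is the exact inverse of the forward convolution
(tested to 1e-8); with zero glycation it is the identity. This is a
deliberately simple linear-deconvolution formulation of the correction; it
does not model interactions between glycation propensity and glycoform
identity.

## 3. Compositional statistics

Fractional abundances live on the simplex, so Euclidean methods are applied
only after the centered log-ratio transform
`clr(x)_k = ln(x_k / g(x))` (row geometric mean `g`), which produces
zero-sum rows and is invariant to rescaling of the raw parts. Zeros are an
error under the default policy (the intended data contain none); an
explicit `replace` policy substitutes a small delta (default 0.01 percent)
and renormalizes, with a warning, for exploratory use.

* **PCA** is covariance PCA of the clr matrix (correlation PCA would
  re-weight glycoforms and break the clr geometry). Component signs are
  fixed by making the largest-magnitude loading of each component positive.
* **Spearman sample correlations** correlate entire glycan profiles
  between samples, so they are invariant to any strictly monotone
  distortion of a profile; constant profiles are flagged `NA`.
* **PERMANOVA** partitions the Gower-centered squared Euclidean distance
  matrix by sequential (Type-I) hat-matrix projections, term order as
  given (phase, then strategy, interaction last). Pseudo-F per term uses
  the residual of the full model. P-values permute samples freely with the
  add-one convention `p = (#{F* >= F} + 1)/(n_perm + 1)`; the minimum
  reportable p is `1/(n_perm + 1)`. The engine accepts an explicit
  permutation matrix, which the tests use to compare it against exhaustive
  enumeration; its sums of squares and F statistics are cross-checked
  against an independent implementation (`vegan::adonis2`). On a
  one-dimensional response the pseudo-F reduces exactly to the classical
  one-way ANOVA F.
* **Dispersion homogeneity** measures each sample's Euclidean distance to
  its group centroid in the full coordinate space and permutes group labels
  of those distances under an ANOVA-F statistic. Centroids (not spatial
  medians) were chosen: they make the distances exactly the within-group
  residual geometry of the PERMANOVA model being diagnosed; the
  spatial-median variant is more robust to outliers but tests a slightly
  different null.

## 4. Differential contrasts

Each glycoform's clr values are fit with an OLS cell-means model over
strategy × phase cells (every cell needs >= 2 replicates; empty cells are a
rank-deficiency error naming the cells). Contrasts of cell means — stationary
vs exponential within strategy, strategy vs strategy within phase — are
tested with empirical-Bayes moderated t-statistics by default: per-glycoform
residual variances are shrunk toward a scaled inverse-chi-square prior fit
by matching the first two moments of the log variances (trigamma inversion
by Newton iteration), with degrees of freedom augmented by the prior df.
The implementation is checked against `limma` on identical designs.
Moderation is toggleable; with it off, t and p match the classical pooled
two-sample t exactly.

Effects are contrasts on the natural-log clr scale divided by `ln 2` and
reported as log2 fold changes — the natural convention when clr effects are
displayed as log2FC, and switchable in principle by multiplying back.
P-values are two-sided and BH-adjusted **within one comparison** (one
contrast across glycoforms), mirroring per-panel presentation; stars at
adjusted p < 0.05 / 0.01 / 0.001.

## 5. Gated univariate comparisons

For scalar process quantities (titers, IVCD, rates, indices) the
comparison procedure first checks assumptions at a fixed gate alpha of
0.05: Shapiro–Wilk on the one-way ANOVA residuals and Levene's test
(median-centered). Both pass → ANOVA + Tukey HSD; otherwise
Kruskal–Wallis + Dunn's test. Dunn's pairwise z statistics use mean ranks
with the standard tie correction; its multiple-comparison correction is BH
by default (Bonferroni and Holm available) since the correction family for
Dunn is a free choice here. Comparisons against a reference strategy and
all-pairs mode are both supported. The gated procedure holds its nominal
type-I error in null simulation (tested over 500 replicates).

## 6. The study simulator

The generator encodes the study conditions of a seven-strategy fed-batch
screen: STD and STD+ (48-h feeds, glucose replenished to 8 g/L), LoG and
LoG+ (48-h, 4 g/L), HiF (24-h, 4 g/L), HIP and HIP+ (24-h, 2 g/L,
pH-triggered), the "+" variants adding a Gal+ supplement (1.25 mM galactose
per feed plus manganese, the latter folded into the galactosylation shift).
Feeding starts day 3; feeds of 5% v/v (48-h strategies) or 2.5% v/v (daily)
dilute the culture; 4 replicates for the 48-h strategies and 3 for the
daily ones; 11-day horizon with glycoform sampling at day 5 (exponential)
and day 10 (LoG/LoG+) or 11 (others, stationary).

**Culture model.** The state (volume, VCD, viability, glucose, lactate,
galactose, titer) advances in daily steps: growth is exponential within the
day at a Monod rate on glucose with reduced-efficiency support from lactate
and galactose, damped by a carrying capacity (`vcd_max` 25e6 cells/mL,
needed to reproduce realistic peak densities of ~17–26e6 while glucose is
replete). Substrate consumption and titer accrual are booked against the
daily *trapezoid* of VCD rather than a forward-Euler endpoint: this keeps
the daily step granularity while making the discrete dynamics exactly
consistent with the trapezoid-based estimators of Section 1, so on
noise-free output the estimated `q_P` and `q_GLC` equal the generating
values (a forward-Euler endpoint update would introduce an O(mu^2)
discrepancy of ~3% at mu = 0.65/d). The cell-specific glucose rate is
`q_glc_maint + q_glc_growth * mu/mu_max` (80 + 220 pg/cell/d); lactate is
produced at 5 mM per g/L glucose consumed before the metabolic shift
(day 5) and 0.3 after, and consumed post-shift at up to 2 pmol/cell/d with
Michaelis saturation; pH is a phenomenological decreasing function of
lactate (7.6 − 0.025/mM), which gives the HIPDOG-like strategies their
characteristic cycle: early lactate pushes pH below the 7.2 trigger and
blocks glucose additions for ~3 days, lactate consumption then raises pH
above threshold and daily glucose feeding resumes, each feed preceded by a
pH check. Viability and VCD decay (2/d at full starvation, with a 25%
tolerated unmet-demand fraction) once the day's carbon demand goes
substantially unmet — this reproduces the low-glucose collapse (LoG
viability falls from day ~8) while letting cyclically-depleted strategies
survive, and Gal+ galactose measurably delays the LoG+ collapse. Glucose
mass balance (initial + fed = consumed + sampled + residual) closes to
1e-9 by construction and is asserted in tests. Optional multiplicative
log-normal measurement noise is applied to recorded values only.

**Glycoform model.** Replicate compositions are drawn in clr space
(logistic-normal — the standard compositional noise model):
baseline + `delta_gal`·(galactosylated indicator) for Gal+ samples
+ `delta_fuc`·(fucosylated-arm fraction) − `delta_afuc`·(afucosylated
indicator) for stationary samples + N(0, `sigma_clr`), then inverse-clr to
percentages. Defaults `delta_gal = delta_fuc = delta_afuc = 0.3` and
`sigma_clr = 0.1` set the effect-to-noise ratio to 3. The baseline
8-species vocabulary (dominated by G0F ⋅ G0F at 45.5%) yields a
galactosylation index near 20% unsupplemented and ~23% under Gal+. Note
that clr re-centering subtracts the mean shift: the Gal+ effect raises all
galactosylated species and necessarily lowers the clr values of the
others — sign-recovery checks therefore evaluate the mean log2FC over
galactosylated species.

**Glycation model.** The per-site glycation probability is a bounded
linear function of the antibody's cumulative residual-glucose exposure,
`p = min(pmax, 1.4e-3 * integral(glucose dt))`, and the hexose-count
distribution is binomial with 3 trials, giving a glycation index of
`100 p`. The default slope puts the stationary-phase study average near
5%.

**What the generator does not emulate.** Technical (HPLC-MS) replication
and quantification error; phase-dependent dispersion (the same `sigma_clr`
is used in both phases, so real stationary-phase heterogeneity is not
reproduced and dispersion tests on simulated data are expected to be
null); strategy × phase interaction structure beyond the additive shifts;
nucleotide-sugar metabolism, osmolality, amino acids, and temperature; and
sialylated or high-mannose species outside the seven-token vocabulary.
Passing recovery tests on this generator therefore demonstrates estimator
and inference correctness under the encoded effect structure — not that
real cultures obey these dynamics.

## 7. Problem sizes and numerical conventions

The test suite exercises the permutation engine with 199–999 permutations,
type-I error calibration with 500 null replicates, and effect-direction
recovery with 100 simulation seeds; the acceptance script uses 999
permutations for the study-level PERMANOVA and 50 seeds for recovery
rates. Abundance row sums are enforced to 1e-9, clr row sums to 1e-10, SS
decompositions verified to 1e-10. All file outputs round numerics to 6
significant digits for diffability; permutation engines take explicit
integer seeds and restore the caller's RNG state. Degenerate inputs
(all-zero samples, windows with fewer than two points, groups of size one,
constant matrices, zero-variance profiles) produce errors or flagged
missing values as documented rather than silent results.

## 8. Known limitations

The hexosylation-bias correction assumes glycation–galactosylation
independence and redistributes within-offset mass proportionally to
observed abundances, which is undetermined when several species share a
galactose count and have zero observed abundance. The q_GLC window model
relies on the post-feed replenishment target for daily-fed strategies; if
actual post-feed concentrations deviate from target this point is
mis-specified. PERMANOVA uses free permutations; designs needing
restricted permutation (e.g., repeated measures) are out of scope, as are
non-Euclidean dissimilarities.
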