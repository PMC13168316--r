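# glycofeed

Analysis pipeline for fed-batch CHO bioprocess studies of monoclonal
antibody N-glycosylation. The package targets process scientists and
analytical chemists who vary **feeding strategies** (feed interval, glucose
replenishment target, galactose/manganese "Gal+" supplementation, including
a pH-triggered HIPDOG-like regime) and want to quantify the downstream
effects on culture performance and on the antibody's Fc N-glycan profile.

It covers four stages:

1. **Kinetics** — cell-specific rates from daily culture time courses:
   specific growth rate `μ_i = Δ ln(VCD) / Δt`, trapezoidal integral viable
   cell density `IVCD_i = ½(VCD_{i−1}+VCD_i)Δt` and its running sum,
   lactate rate `q_LAC = ΔLAC/ΔIVCD` (pmol·cell⁻¹·d⁻¹, 48-h intervals),
   cell-specific productivity `q_P = ΔP/ΔIVCD` (pg·cell⁻¹·d⁻¹, 24-h
   intervals, plus a day 3–11 process average), and the glucose consumption
   rate `q_GLC` as the negative slope of the per-feeding-window regression
   `c_GLC = slope · IVCD_sum + d + ε`.
2. **Glycoforms** — parsing of the paired-glycan nomenclature
   ("G1F ⋅ G0F" = the two Fc N-glycans of one antibody; G0/G1/G2 = 0/1/2
   terminal galactoses, trailing F = core fucose, "none" = unoccupied
   site), fractional-abundance tables (percent, rows sum to 100), the
   **galactosylation index**
   `100 · Σ_j A_j g_j / Σ_j A_j d_j`
   (abundance-weighted occupancy of galactosylation sites, two per present
   glycan), the **glycation index**
   `100 · Σ_i g_i f_i / Σ_i s_i f_i` with `s_i = 3` backbone hexose sites,
   and a non-negative least-squares deconvolution that corrects the
   intact-level **hexosylation bias** (galactose and backbone glucose
   adducts are both +162 Da) using the glycation distribution measured on
   deglycosylated antibody.
3. **Compositional statistics** — centered log-ratio (clr) transform,
   covariance PCA, sample-by-sample Spearman correlations, PERMANOVA on
   Euclidean distances with sequential (Type-I) sums of squares and free
   permutations, multivariate dispersion homogeneity, per-glycoform
   moderated linear-model contrasts (empirical-Bayes variance shrinkage,
   BH-adjusted p, significance stars), and a gated univariate procedure
   (Shapiro–Wilk + Levene → ANOVA/Tukey or Kruskal–Wallis/Dunn).
4. **Simulation** — a seeded fed-batch study generator for the seven
   packaged feeding strategies with known ground-truth kinetic and glycan
   parameters, used throughout the test suite for parameter- and
   effect-recovery checks.

## Worked example

```r
library(glycofeed)

# indices from first principles
tab <- glycoform_table(matrix(c(50, 50), 1,
  dimnames = list("s1", c("G0F . G0F", "G1F . G1F"))))
galactosylation_index(tab)
#> s1
#> 25
glycation_index(glycation_profile(c(50, 50, 0, 0)))
#>       s1
#> 16.66667

# a full synthetic feeding-strategy study and its multivariate analysis
study <- generate_study(seed = 1)
study
#> glyco_study: 25 culture replicates, 50 glycoform samples, seed 1

clr <- clr_transform(study$glycoforms)
permanova(clr, c("phase", "strategy"), n_perm = 999, seed = 1)
#> PERMANOVA (Euclidean, sequential SS, 999 permutations)
#>      term df    ss      f     r2     p
#>     phase  1 3.843 49.998 0.3954 0.001
#>  strategy  6 2.648  5.742 0.2724 0.001
#>  Residual 42 3.228     NA 0.3322    NA
#>     Total 49 9.719     NA 1.0000    NA
```

The 50/50 mixture of an agalactosylated (`g_j = 0`) and a
mono-galactosylated-per-arm (`g_j = 2`) glycoform pair occupies
`(50·0 + 50·2)/(50·4 + 50·4) = 25%` of its galactosylation sites; a
glycation profile with half the antibody carrying one of three possible
backbone hexoses gives `50/300 = 16.7%`. In the simulated study, culture
phase and feeding strategy each explain a significant share of the clr-space
variation (permutation p = 0.001 for both terms), driven by the generator's
Gal+ galactosylation shift and stationary-phase fucosylation shift.

Per-sample galactosylation indices of the same study
(`galactosylation_index(study$glycoforms)`) average ~23% for the Gal+
strategies versus ~20% for their unsupplemented counterparts.

A thin command-line wrapper is included
(`inst/cli/glycofeed.R`, or `glyco_cli()` from R) with subcommands
`simulate`, `kinetics`, `glyco-indices`, `correct`, `multivariate`,
`difftest`, `groupstats`, `report`.

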