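# morphherit

Quantitative genetics of body shape and size in half-sib breeding designs,
built for common-garden experiments on fishes (the motivating system is
hatchery salmonids reared in families with known parentage). The package
answers the question: *how much of the variation in body shape, length,
weight and condition among families is additive genetic?*

It implements the complete analysis chain as composable, pipe-friendly
functions:

- **Geometric morphometrics** — TPS landmark file I/O, centroid size,
  generalized Procrustes analysis (GPA), thin-plate-spline bending energy,
  partial warp scores (non-uniform + uniform components) and relative warps
  (principal components of the partial warp scores). For k = 13 landmarks in
  2-D this yields 2k − 4 = 22 shape axes.
- **Size and condition phenotypes** — pooled weight–length regression
  log₁₀W = a + b·log₁₀L, relative condition factor Kₙ = W/W′ with
  W′ = 10^(a + b·log₁₀L), and development rate in accumulated temperature
  units (ATU).
- **Pedigrees and relationships** — the three classic half-sib breeding
  designs (nested, partial factorial, split egg lots) and the additive
  numerator relationship matrix **A** by the tabular method.
- **The animal model** — REML estimation of variance components under
  y = Xb + Za + (c) + (f) + e with cov(a) = **A**·V_a, optional iid dam (V_m)
  and full-sib family (V_c) terms; heritability h² = V_a/V_p and dam effect
  m² = V_m/V_p with delta-method standard errors; likelihood-ratio tests of
  each component against χ²₁; bivariate REML for additive genetic
  correlations r_g = cov_a/√(V_a1·V_a2).
- **Multivariate strain statistics** — MANOVA (Wilks' Λ = |W|/|W+B| with
  Rao's F), homogeneity-of-slopes MANCOVA against log₁₀ centroid size,
  leave-one-out linear discriminant reclassification with equal priors, and
  split-plot repeated measures on family-mean warp scores.
- **A synthetic-study generator** — complete simulated experiments (70
  half-sib families across three strains by default) with known variance
  components, latent shape effects along fixed deformation directions,
  allometric growth, nuisance digitization transforms and landmark noise, so
  every stage of the pipeline is validated by parameter recovery.

## Worked example

Simulate a 30-family partial-factorial study with a single latent shape
trait of true heritability 0.5, run the morphometric chain and estimate h²
of the leading relative warp:

```r
library(morphherit)
library(dplyr)

params <- sim_params(
  designs = list(assinica = cross_design(15, 10, "partial_factorial",
    dams_per_sire = 3, sires_per_dam = 2)),
  n_per_family = c(8L), periods = 1L,
  shape_vc = list(c(V_a = 0.5, V_m = 0, V_c = 0, V_e = 0.5)),
  strain_shape_shift = c(assinica = 0), period_drift = 0
)
st <- simulate_study(params, seed = 42)
#> <sim_study: 265 pedigree members, 30 families, 240 measurements over 1 period(s)>

ws <- st$landmarks |> filter(period == 1) |> select(-period) |> relative_warps()
#> <warp_scores: 240 specimens, 22 axes; leading variance fractions 0.829, 0.013, 0.012, 0.011>

d   <- inner_join(st$phenotypes, ws$relative[c("id", "rw1")], by = "id")
fit <- animal_model(d, "rw1", st$relationship, id = "fish_id")
tidy(fit)
#> # A tibble: 2 × 4
#>   term     variance proportion     se
#> 1 additive 0.000214      0.530  0.166
#> 2 residual 0.000190      0.470 NA

lrt_varcomp(fit, drop_random_term(fit, "additive"))
#> statistic 39.7, df 1, p = 3.0e-10
```

The single simulated shape axis dominates the shape space (83% of variance
on RW1), and the animal model recovers its heritability (ĥ² = 0.53 ± 0.17
against a true value of 0.5) with a decisive likelihood-ratio test. The
condition-factor identities hold on the same data: refitting the pooled
weight–length regression gives b̂ = 2.99 against the generating allometric
exponent 3, and mean Kₙ = 1.001.

`run_pipeline()` chains all stages (per-period relative warps, condition,
per-strain and pooled heritabilities with LRTs, MANOVA/MANCOVA, DFA,
repeated measures) from a single declarative config and returns tidy report
tables; `write_fixture_study()` emits a complete study as TPS + CSV + JSON
files, byte-identical per seed.

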