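---
title: "Methods: from landmarks to heritability in half-sib designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from landmarks to heritability in half-sib designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the models it fits,
the assumptions they carry, the numerical choices made where the design was
genuinely open, and what the validation suite does and does not establish.

## The problem

Common-garden breeding experiments on fishes produce three kinds of data:
digitized landmark configurations describing body shape, simple size and
condition measurements (length, weight), and a pedigree linking every fish
to its sire and dam. The scientific question is how much of the phenotypic
variation — in shape axes, length, weight, condition — is additive genetic,
i.e. available to natural or artificial selection. `morphherit` covers the
whole chain: shape variables from raw landmarks, condition phenotypes,
pedigree relationships, and REML animal-model variance components with the
accompanying multivariate strain comparisons.

## Geometric morphometrics

**Superimposition.** `gpa()` performs generalized Procrustes analysis:
every configuration is centered, scaled to unit centroid size, and rotated
onto the running consensus by the least-squares orthogonal rotation
(determinant +1, so reflections — which change shape — are never applied);
the consensus is the renormalized mean of the aligned configurations and
the cycle repeats until its root-mean-square displacement falls below
`tol = 1e-10`. This is *partial* Procrustes superimposition (aligned
specimens keep unit centroid size; no extra scaling during rotation),
matching the defaults of the standard relative-warps software. Centroid
size is root summed squared deviations of the landmarks from their
centroid; the formulation via summed squared inter-landmark distances
differs only by the constant factor √k at fixed k and yields identical
shape variables.

Two deliberate simplifications are documented rather than hidden. First,
no projection from the Procrustes hemisphere to a tangent plane is applied
beyond the alignment itself: at within-population scale (Procrustes
distances of order 10⁻²) the difference is far below the tolerances of any
test in this package. Second, output orientation is made deterministic by
rotating the converged solution onto the principal axes of the consensus,
with a 180° fix so the landmark of largest |x| lies on the positive axis.

**Warp scores.** `warp_basis()` builds the thin-plate-spline bending energy
matrix from the consensus (kernel U(r) = r² log r²; the bending energy is
the upper-left k×k block of the inverted TPS system). Its eigenvectors are
the principal warps; exactly k − 3 eigenvalues are nonzero in 2-D and
affine transforms of the consensus have zero bending energy. Each
specimen's deviation from the consensus is projected onto the principal
warps (x and y components per warp) and onto a two-dimensional uniform
basis, giving 2k − 4 partial warp scores; for the 13-landmark scheme, 22.
The uniform component is computed as the orthogonal projection of
residuals onto the affine shape subspace at the consensus (the affine
directions X·Bᵀ with the similarity directions swept out) — several
uniform-estimation variants circulate in the geometric-morphometrics
literature, and this complement construction is the cleanest of the
standard options; all span the same two-dimensional space.

**Relative warps** are the principal components (SVD about the mean) of
the partial-warp score matrix. With the weighting exponent α = 0 (the
default, and the only setting exercised by the validation suite) they
coincide with principal components of the aligned coordinates themselves.
Axes are ordered by variance explained; variance fractions sum to one.
Signs are resolved by mapping each axis loading back into landmark space
and making its largest-magnitude coordinate positive — resolving the sign
in landmark space (rather than in the partial-warp basis) matters because
principal warps inside nearly degenerate bending-energy eigenspaces are
individually arbitrary even though the shape subspace they span is not.
α ≠ 0 is supported but carries no validation guarantees.

## Condition and development phenotypes

The weight–length model is ordinary least squares of log₁₀W on log₁₀L,
fitted once on the pooled sample (all strains and periods together): the
relative condition factor Kₙ = W/W′, with W′ the standard weight predicted
at the fish's length, is only comparable across groups when a single
population regression defines W′. Base-10 logs follow the
condition-factor literature. By construction the mean of log₁₀Kₙ over the
fitting sample is exactly zero, so the geometric mean of Kₙ is 1 — both
are asserted in tests. Development rate is accumulated temperature units:
the partial sum of daily mean temperatures from fertilization through
hatch, with sub-daily series averaged per day first.

## Pedigrees and the relationship matrix

`cross_design()` reproduces the three half-sib designs used in the
motivating experiment — 12 dams × 5 sires nested (12 families), a
15 × 10 partial factorial with each sire on 3 dams and each dam under 2
sires (30 families), and 20 dams × 10 sires with eight egg lots split
between two sires (28 families); 70 families in all. Partner assignment
(which sires take 3 rather than 2 dams; which dams are split) is
deterministic by label order unless a seed is supplied, and
every family-count and relationship-structure property is invariant to
that choice. `additive_relationship()` uses the tabular method
(A[i,i] = 1 + F_i, A[i,j] = ½(A[j,sire] + A[j,dam])), with unknown
parents treated as unrelated non-inbred founders; dense O(n²) storage is
appropriate at study sizes well under a few thousand individuals. A
brute-force coancestry recursion serves as the independent oracle in the
tests.

## The animal model

`animal_model()` maximizes the standard restricted log-likelihood

&nbsp;&nbsp;ℓ(θ) = −½[(n − p)·log 2π + log|V| + log|XᵀV⁻¹X| + yᵀPy],

over non-negative variance components, where V = V_a·ZAZᵀ + V_m·Z_cZ_cᵀ +
V_c·Z_fZ_fᵀ + V_e·I and P is the usual REML projection. Fixed effects use
reference-level coding (population mean; maturation status where it
varies, i.e. in later sampling periods; strain for pooled-strain fits);
aliased columns are a hard error naming the column.

Numerical choices:

- **Optimizer.** Bound-constrained quasi-Newton (L-BFGS-B) on
  log-variance parameters scaled by the residual variance of the
  fixed-effects-only fit, from three spread starting values (balanced,
  residual-dominated, genetic-dominated); the best restricted likelihood
  wins. Components below 10⁻⁸ of the phenotypic scale are snapped to the
  boundary.
- **Fast path.** When the model contains a single correlated term plus
  residual — the workhorse configuration in simulations — V is
  diagonalized once through the eigendecomposition of ZAZᵀ, making each
  likelihood evaluation O(n). Models with dam or family terms use dense
  Cholesky algebra. Both paths evaluate the identical likelihood and are
  pinned to a brute-force dense evaluation (generic `solve`/`determinant`)
  in the oracle tests, to 10⁻⁸.
- **Standard errors.** Delta-method SEs of h² and m² from a
  central-difference Hessian of the restricted likelihood on the log scale
  (step 10⁻⁴), computed over the components away from the boundary; at the
  boundary the SE is reported as `NA` rather than a spurious zero.
- **Likelihood-ratio tests.** `lrt_varcomp()` reports
  max(0, 2Δℓ) against χ²₁. Because the null value of a variance component
  lies on the boundary of its parameter space, the plain χ²₁ p-value is
  conservative (asymptotic size ≈ 2.5% at nominal 5%); it is nevertheless
  the default, as it is the convention in the applied literature this
  package serves. The calibrated 50:50 χ²₀:χ²₁ boundary mixture is
  available via `boundary = TRUE`, and it is this variant whose null
  rejection rate the calibration suite verifies at 5% ± 2.5%.
- **Confounding.** In a purely nested design the full-sib family
  partition coincides with the dam partition, and a family term is then
  completely confounded with the dam/additive structure; `animal_model()`
  detects this (family ↔ dam partitions identical) and refuses the term
  with an explanatory error instead of returning an unidentified fit.
- **Genetic correlations.** `genetic_correlation()` fits the bivariate
  additive + residual model by REML with Σ_a, Σ_e kept positive definite
  through a log-sd / atanh-correlation parameterization, starting from the
  univariate fits. The 2n × 2n system block-diagonalizes into n 2×2 blocks
  under the eigen-rotation of ZAZᵀ, so evaluations stay O(n). The LRT
  pins cov_a = 0 in the constrained fit (one degree of freedom).
- **Pooled-strain fits.** Whether pooled analyses should carry dam or
  family terms is genuinely open; the pipeline defaults to additive-only
  with strain as a fixed effect, and the `random` field of the config
  overrides it.

## Multivariate strain statistics

Wilks' Λ = |W|/|W + B| with Rao's F approximation is computed directly
from the scatter matrices; the homogeneity-of-slopes MANCOVA forms Λ from
the residual scatters of the separate-slopes versus common-slope
multivariate linear models (the group × covariate interaction, the test
for allometric differences among strains). When a score matrix would make
the within-group scatter singular, the scores are truncated to their
leading principal components with a logged message, keeping the test
defined while preserving as much of the shape space as the sample size
supports. Discriminant reclassification uses pooled-covariance LDA with
**equal priors** (group sizes are breeding-design artifacts, not
prevalences; note this diverges from software whose default priors are
proportional) and leave-one-out cross-validation, optionally after an
equal-count seeded subsample per family so large families do not dominate
the rule. Repeated measures on family means are analysed per warp as a
split-plot ANOVA — strain between families, period within — with no
sphericity correction (the uncorrected split-plot is the transparent
default, and is exactly calibrated in the simulated nulls used here, which
have compound symmetry by construction). Families seen in fewer than two periods are
dropped with a warning.

The pipeline computes one relative-warp space per sampling period (all
strains pooled), then splits by strain for the genetic analyses; the
repeated-measures stage, which needs commensurate axes across periods,
uses a single shape space spanning all periods.

## The synthetic-study generator

`simulate_study()` emulates the structure of the motivating experiment:
the three breeding designs above (70 families); three sampling periods
with per-family sample sizes 10, 8 and 5 (declining with mortality and tag
loss, as in the real sampling scheme of roughly 660 → 496 → 348 fish);
latent shape traits with additive + dam + family + residual components
drawn with exact pedigree covariance (breeding values via the PSD square
root of A); shape effects expressed along fixed orthonormal, centered,
non-affine deformation directions (by default the two lowest-bending-energy
principal warps of a hand-coded 13-landmark salmonid template, applied as
dorso-ventral deformations — body-depth-like and caudal-peduncle-like
axes); allometric weight from length with log-scale genetic and
environmental deviations; maturation at rate 0.2 in later periods with a
small negative length effect; and nuisance digitization transforms
(rotation ±π, translation, scale 0.5–2) plus iid landmark noise
(sd 0.002 Procrustes units, a realistic digitization error an order of
magnitude below the simulated shape signal of sd 0.02). Because latent
traits are scalar scores along fixed directions, the true heritability of
a shape direction is exactly V_a/(V_a + V_m + V_c + V_e), recorded in the
truth file. Estimated warps need not coincide with the generating
directions, so recovery is asserted both on scores projected onto the true
basis (`project_shape_direction()`) and on the leading relative warp.

One master seed is split into independent sub-seeds per generator stage,
so adding a stage never perturbs earlier draws and fixture trees are
byte-identical per seed.

What the generator deliberately does **not** emulate: measurement of the
same individual across periods (fish are resampled per period, as in the
tag-by-family-only design it mirrors), genotype-by-environment interaction,
selection or mortality correlated with phenotype, non-normal trait
distributions, and landmark digitization error that is correlated across
landmarks. Passing recovery tests therefore demonstrates correctness of
the estimation chain under the stated model, not robustness to these
real-data complications.

## Validation problem sizes

The recovery and calibration suites run at the sizes of the experiment
they emulate: the 30-family partial factorial with 8 offspring per family
for univariate recovery (50 replicates at h² ∈ {0.2, 0.5, 0.8}, mean
error < 0.1 and two-SE coverage within 85–99%), 30 replicates for
m² = 0.25, 15 replicates of the 30 × 10 design for r_g = 0.6, 25
end-to-end landmark replicates at h² = 0.5 (tolerance 0.15), and 200
replicates per null for test calibration (100 for the DFA chance-rate
check). These counts balance Monte-Carlo error against a test suite that
stays fast enough to run routinely.

## Known limitations

- 2-D landmarks only; no sliding semilandmarks; no deformation-grid
  graphics beyond the consensus overlay plot.
- The REML fitter targets study-scale problems (dense algebra, n up to a
  few thousand); it is not a sparse mixed-model engine.
- Multi-trait models stop at the bivariate case; no Bayesian/MCMC animal
  models or genomic relationship matrices.
- χ²₁ default p-values for variance components are conservative at the
  boundary (see above); users wanting calibrated tests should pass
  `boundary = TRUE`.
- The uniform-component estimator is one of several equivalent-rank
  variants in circulation; scores on the two uniform axes (but not the
  subspace they span, nor any relative warp with α = 0) depend on that
  choice.
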