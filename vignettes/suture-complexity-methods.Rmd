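---
title: "Suture complexity and phylogenetic comparative methods in suturemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suture complexity and phylogenetic comparative methods in suturemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suturemorph)
```

`suturemorph` scores the geometric complexity of 2D cranial suture traces and
relates those scores to ecological and morphological covariates while
accounting for phylogeny. This vignette is the package's own account of the
models it fits, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic validation does and
does not demonstrate.

## From digitised trace to semi-landmarks

A suture arrives as an ordered open polyline of digitised points (CSV or a
TPS landmark dialect). Traces differ in point count, so each is resampled to
a fixed number of equidistant semi-landmarks — 250 by default, matching the
sampling density typical for a mammalian suture at μCT resolution. Resampling
uses cumulative Euclidean chord length with linear interpolation: point *k*
sits at arc position *kL/(n−1)*, and the original endpoints are kept exactly.
Consecutive duplicate points are dropped (with a warning) beforehand because
zero-length segments break the interpolation.

One numerical subtlety: resampling measures arc length along the *current*
polyline, so re-resampling an already-resampled curve moves points only at
second order in the chord-versus-arc contraction (empirically below 1e-5 for
smooth curves at n = 250, and exact for straight segments). The tests pin
this down rather than pretending the operation is exactly idempotent.

Digitisation may start at either end of a suture. Before joint alignment,
each curve is re-ordered so the endpoint chord points into the non-negative-x
half-plane (ties broken on y). Both complexity metrics are reversal-invariant,
so this only standardises the Procrustes frame. Sources digitised with y
increasing downwards can be flipped on read (`flip_y`), keeping one internal
convention so signal signs are well defined.

## Generalised Procrustes alignment

Configurations (2D suture semi-landmarks or 3D cranial landmark sets) are
translated to the origin, scaled to unit centroid size — centroid size,
`sqrt(Σ ‖xᵢ − x̄‖²)`, is kept separately as the geometric size variable — and
iteratively rotated onto the evolving mean shape by orthogonal Procrustes
superimposition. Three choices are deliberate:

* **No sliding.** Semi-landmarks are treated as fixed points. Bending-energy
  sliding is a reasonable alternative, but fixed points keep the arc-length
  parameterisation (which the complexity metrics rely on) intact.
* **Proper rotations only.** Reflections are disallowed (determinant +1),
  since sutures and skulls have defined anatomical chirality.
* **Canonical output frame.** GPA leaves a global rotation undetermined; we
  rotate the converged set into the principal-axes frame of the mean shape
  with deterministic axis signs, so the output is invariant (to ~1e-8) to
  the pose in which any specimen was digitised.

Convergence is declared when the root-mean-square change of the mean shape
drops below 1e-10, with a cap of 100 iterations. For sets of *similar*
shapes — the realistic regime — this converges in a handful of iterations.
For completely unrelated random configurations the mean is nearly degenerate
and convergence can be slow; the function then warns and returns
`converged = FALSE` with the per-iteration objective trace so the user can
judge.

Shape PCA is an eigen-decomposition of the covariance of the vectorised
aligned coordinates; components with numerically null variance (below
1e-12 of the leading eigenvalue) are dropped so variance fractions sum to 1
over the retained components.

## The two complexity metrics

**Sinuosity index.** `SI = total path length / endpoint distance ≥ 1`. It is
invariant to similarity transforms and point-order reversal, and is most
sensitive to the *amount* of interdigitation.

**PSD score.** The curve is first rigidly mapped so its endpoint chord lies
on the x axis with the first point at the origin; the 1D signal is the
sequence of signed perpendicular deviations from the chord. This definition
was an open choice — the alternative of using raw y coordinates in some
external frame would make the score depend on placement — and it guarantees
a straight suture maps to the exactly-zero signal, giving both metrics the
same baseline. A short-time Fourier transform then slides a tapered window
along the signal; for each window the power spectrum is computed with
Welch-style window-energy normalisation, the DC bin is excluded (placement
must carry no power), the remaining bins are summed, and the score is the
mean across windows.

Defaults: window 50 samples, overlap 0.5, Hann taper. With n = 250 this
yields 9 windows — enough averaging to stabilise the score while keeping
frequency resolution useful for interdigitation wavelengths of a few percent
of the suture length. All three are exposed as arguments. The score is
quadratic in signal amplitude (doubling the amplitude quadruples it), which
the tests verify exactly on pure sinusoids.

Because both metrics are computed on Procrustes-aligned curves, they are
dimensionless. SI and PSD deliberately capture different axes of complexity:
on a family of sinusoids with amplitude × frequency held constant (constant
arc length), SI is nearly constant while the PSD score changes severalfold —
a property test in the suite.

## Phylogenetic machinery

The Brownian-motion covariance `V[i,j]` is the shared root-to-MRCA path
length of tips *i* and *j* (computed via `ape`, and cross-checked in tests
against an independent recursive path walk). Pagel's λ rescales off-diagonal
entries only; the upper bound is fixed at 1, the standard definition on
ultrametric time-scaled trees. Zero-length terminal branches are allowed but
warn, since they risk a singular V; no silent regularisation is ever applied.

* **PGLS** solves `β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y` via a Cholesky whitening of V.
  Standard errors use `σ̂² = rᵀV⁻¹r/(n−q)` and t-tests are two-sided on
  `n − q` degrees of freedom (the usual GLS convention; q = 2 for a simple
  regression). `lambda_mode = "ml"` profiles λ over [0, 1] by bounded scalar
  optimisation (tolerance 1e-8, endpoints checked explicitly so boundary
  optima are exact).
* **Pagel's λ ML** maximises the multivariate-normal likelihood with the
  mean profiled out by GLS; it refuses constant trait vectors, whose
  likelihood is degenerate.
* **Phylogenetic ANOVA** compares the observed one-way F against F values
  from Brownian simulations on the tree. The simulation rate is the ML
  estimate from the data (`σ̂² = rᵀV⁻¹r/n` around the GLS grand mean) — an
  assumption worth stating, though F is location-scale invariant, so the
  rate choice does not affect the null distribution. The p-value uses the
  add-one estimator `(1 + #{F_sim ≥ F_obs})/(n_sim + 1)`, so
  `p ≥ 1/(n_sim+1)` by construction. Pairwise pooled-variance t statistics
  are referred to their own simulated two-sided nulls and Holm-adjusted —
  Holm is also the adjustment for the parametric pairwise table; both are
  configurable.
* **Procrustes PGLS** whitens the vectorised shapes and the design matrix by
  the inverse matrix square root of V (eigendecomposition), fits least
  squares there, and reports `r² = SS_model/SS_total` in the transformed
  space. Significance is by residual randomisation (RRPP): residuals of the
  intercept-only reduced model are permuted across species in the
  transformed space, the statistic recomputed, and the add-one estimator
  applied. With a single continuous predictor the fitted values are rank one
  after centring, so the PCA of fitted values reports PC1 ≈ 100%; with
  richer designs the fitted-component variance fractions become informative.
* The ANOVA-versus-PANOVA choice is reported side by side: residual λ of the
  parametric fit is estimated, and the preferred model is flagged as
  standard ANOVA when λ falls below 0.5 (low signal means the Brownian
  assumption buys nothing), PANOVA otherwise. Both results are always
  emitted; the flag is advisory.

One-way ANOVA itself, the Shapiro–Wilk normality check, and multiple-testing
adjustment are delegated to base R (`lm`/`anova`, `shapiro.test`,
`p.adjust`) behind validated wrappers; the generalised η² reported is
`SS_between/SS_total`, which is what the generalised effect size reduces to
in a one-way between-subjects design.

## The synthetic study generator

The generator exists so that every stage — file I/O, resampling, GPA,
complexity, statistics — can be exercised on data whose ground truth is
known. Its defaults encode the study conditions the pipeline targets:

* 14 species, one specimen each, 250 semi-landmarks per suture;
* a unit-depth pure-birth tree; three locomotor categories (generalised,
  saltatorial, cursorial; 5/5/4) assigned to *contiguous clades*, which
  induces strong phylogenetic signal in the category — this makes the
  ANOVA/PANOVA comparison meaningful rather than decorative;
* suture form `y = a·sin(2πfx)` with frequency f = 8 and baseline amplitude
  a = 0.02 (SI ≈ 1.2, the modest complexity regime of mammalian sutures),
  plus isotropic digitisation jitter of SD 5e-4 of the chord;
* per-species amplitude = baseline + group offset + Brownian deviation
  (rate 2.5e-5, i.e. SD 0.005 at unit depth), truncated at zero;
* facial tilt (degrees) = 52 + slope × (expected SI − 1) + Brownian noise
  (SD 2°). The expected-SI map is calibrated numerically from the generator
  itself (a cached amplitude grid) rather than from a hand-derived
  arc-length formula. Under the `"strong"` preset the slope is −30°/SI unit
  and cursorial species get a −0.01 amplitude offset; under `"null"` all
  effects are zero;
* body mass is log-normal around 1200 g (roughly 300–4000 g), centroid size
  log-normal around 70, both independent of complexity; burrowing is
  Bernoulli(0.5).

All randomness fans out from one master seed into per-component streams, so
an entire study is reproducible from a single integer, and the package
restores the caller's RNG state after every seeded call.

**What the generator does not emulate.** Real sutures are not sinusoids —
they carry fractal-like irregularity, varying interdigitation wavelength
along the trace, and 3D relief that a 2D projection flattens. There is one
specimen per species, so intraspecific variation is invisible. The 3D
cranial stage is validated with abstract landmark configurations, not
realistic leporid crania. Passing the synthetic suite therefore shows the
*estimators and their error rates* behave correctly under the assumed
generative model; it does not validate the biological adequacy of that model
for any particular taxon.

## Validation design and problem sizes

The statistical validation in the test suite uses these scales, chosen to
make Monte-Carlo error small relative to the tolerances being checked:

* λ recovery: one 128-tip tree, 100 Brownian replicates (mean λ̂ high) and
  100 white-noise replicates (mean λ̂ low);
* phylogenetic ANOVA calibration: 500 null Brownian datasets on the 14-tip
  study design, 500 simulations each, nominal α = 0.05;
* study-level calibration: 200 full synthetic studies under the null preset
  (PGLS type-I error) and 200 under the strong preset (slope-sign
  recovery);
* RRPP calibration: 200 null datasets on a 10-tip tree, 30 shape variables,
  499 permutations each, with a Kolmogorov–Smirnov uniformity check.

Exact identities are tested at tight tolerances (PGLS = OLS on star trees at
1e-8; F = t² at 1e-10; analytic sinuosity values at 1e-3 against quadrature),
and the in-package estimators are cross-checked against independent
references (`nlme::gls` with a Brownian correlation, `phytools::phylosig`,
`phytools::phylANOVA`) on fixed datasets.

## Known limitations

* Complexity is inherently 2D here; genuinely 3D suture complexity is out of
  scope.
* The error structure is Brownian (optionally λ-rescaled); no
  Ornstein–Uhlenbeck or early-burst alternatives.
* λ is constrained to [0, 1]; references that allow λ slightly above 1 on
  some trees will disagree at that boundary.
* Permutation and simulation p-values are exact only up to their add-one
  resolution (`1/(n+1)`); choose `n_sim`/`n_perm` accordingly.
* With 14 species, power for anything but large effects is limited — the
  strong preset is detectable, but real effect sizes near the detection
  boundary will produce unstable model preferences between ANOVA and
  PANOVA.
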