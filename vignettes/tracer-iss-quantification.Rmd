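---
title: "Quantifying interstitial-space microstructure and ISF clearance with tracer-based MRI"
author: "issmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interstitial-space microstructure and ISF clearance with tracer-based MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issmri)
```

## The measurement

A small amount of Gd-DTPA (here 2 µL of 10 mmol/L, i.e. Q = 20 nmol,
pump-infused over 10 min) is injected into deep grey matter. The tracer is
confined to the interstitial space (ISS), spreads by hindered diffusion,
and is cleared from the interstitial fluid (ISF). Since Gd-DTPA shortens
the T1 of surrounding water, serial T1-weighted volumes (baseline plus
0.5–8 h post-injection) show a bright cloud that grows and fades. From that
movie the package estimates:

* **D\*** — effective diffusion coefficient in the ISS (mm²/s),
* **λ = √(D/D\*)** — tortuosity relative to the free-medium coefficient D,
* **k′** — first-order clearance rate constant (1/s),
* **t½** — half-life of the measured in-brain tracer amount (min),
* spreading-region volume curves (mm³ of "lightened" voxels per time).

## Forward model and its assumptions

The concentration of tracer in the ISF follows the porous-medium
diffusion–clearance equation ∂C/∂t = D\*∇²C − k′C with a point source, whose
solution is

$$C(r,t) = \frac{Q}{\alpha}\,(4\pi D^{*} t)^{-3/2}
  \exp\!\left(-\frac{r^{2}}{4 D^{*} t} - k' t\right),$$

with α the ISS volume fraction. Assumptions: the medium is homogeneous and
isotropic at the scale of the tracer cloud (millimetres), clearance is
first-order and spatially uniform, and bulk advection is not modelled
separately — directed ISF flow is absorbed into D\* and k′. Anisotropy,
heterogeneous D\* maps and explicit paravascular pathways are out of scope.

**Infusion timing.** The 10 min infusion is short compared with the first
scan at 30 min, so by default the source is treated as instantaneous with
the model clock started at the infusion midpoint (`t_offset = 300` s,
carried on every concentration series and applied identically during
simulation and fitting). The alternative `source_mode = "extended"`
superposes point sources across the infusion by Simpson quadrature; at the
first scan time the two differ by under 1% in L2 over the field (a few
percent pointwise in the far exponential tail), which the test suite
checks. This quantifies, rather than assumes, the adequacy of the midpoint
approximation.

## Signal model

Enhancement is modelled through the longitudinal relaxation rate
R1(C) = 1/T1 + r1·C and a monotone signal law: by default saturation
recovery, S = S0(1 − exp(−TR·R1)); optionally the inversion-prepared form
S = S0(1 − 2exp(−TI·R1) + exp(−TR·R1)) matching an MPRAGE-style
acquisition. Only monotone invertibility matters downstream; the scanner
settings (TR 1500 ms, TE 3.7 ms, TI 900 ms, flip 12°) are carried as
defaults of `acquisition_params()`.

Defaults chosen once for quantities the protocol does not pin down, with
the reasoning:

| parameter | default | why |
|---|---|---|
| r1 | 3.7 /(mM·s) | typical Gd-DTPA relaxivity at 3 T |
| T1_baseline | 1400 ms | deep grey matter at 3 T |
| S0 | 1000 a.u. | arbitrary signal scale |
| α | 0.2 | classical ISS volume fraction in grey matter |
| D_free | 3.8 × 10⁻⁴ mm²/s | Gd-DTPA in dilute medium at 37 °C; always reported next to λ |
| grid | 64³ × 0.5 mm | holds > 99.9% of tracer mass over 8 h at sham-scale D\* |

**Noise.** Magnitude MRI noise is Rician:
`sqrt((S + σZ₁)² + (σZ₂)²)`. Gaussian noise is a high-SNR limit of this.
All stochastic operations accept a seed and restore the caller's RNG
state, so studies are bitwise reproducible.

## Preprocessing

Frames are aligned to the pre-injection baseline by exhaustive integer-voxel
translation maximising normalised cross-correlation (head-fixed rodent
acquisitions drift at most a voxel or two at 0.5 mm resolution; integer
shifts keep the operation lossless and exactly testable). Registration
requires spatial structure in the baseline; on structure-free synthetic
volumes the estimate is noise-driven, which is why the registration tests
build frames over a smooth synthetic "anatomy".

Baseline subtraction keeps negative increments — clipping them would bias
the background noise estimate, which is taken as the standard deviation of
increments over the eight 5³-voxel corner blocks (tracer-free by
construction; the grid must be large enough that this holds).

**Signal → concentration.** The saturation-recovery law is inverted in
closed form; the inversion-prepared law by monotone interpolation polished
with vectorised Newton steps. Negative increments map to concentration 0.
Two saturation guards apply on noisy data: increments at or above the
signal of `C_max` (default 10 mM) and increments whose remaining headroom
to the law's supremum is below `headroom_snr × σ` are clipped to the
largest reliably invertible concentration and flagged. Near saturation the
inverse map amplifies noise without bound, so those samples carry no usable
concentration information; the flag records exactly where.

## Parameter estimation

`fit_diffusion_model()` fits {log A, log D\*, k′, source position} by
bounded Levenberg–Marquardt jointly over all masked (voxel, time) samples.
Joint space–time fitting is what decouples D\* (spatial spread) from k′
(temporal loss) with ten time points. Bounds: D\* ∈ [10⁻⁶, 10⁻²] mm²/s,
k′ ∈ [0, 10⁻²] /s, source within ±1 mm of the nominal stereotactic site
(needle-placement slack while keeping the problem identifiable). The global
search is a deterministic 4 × 4 log-spaced grid over (D\*, k′) with the
amplitude profiled at each node, followed by LM refinement; 95% CIs come
from the Jacobian at the optimum.

Two design points deserve emphasis, because the obvious alternative fails:

* **Residuals are evaluated in signal space** on noisy data. Inverting a
  saturating T1 law maps symmetric signal noise into heavy-tailed,
  *upward-biased* concentration noise wherever the law flattens (the
  inverse is convex), and unit-weight least squares on such values
  over-estimates the cloud's extent severely. Pushing the model
  concentration through the signal law and comparing with observed
  increments keeps the noise homoscedastic and symmetric; saturated
  samples then contribute exactly the information they contain (almost
  none) without being discarded or distorted. Noise-free series are fitted
  directly in concentration space with unit weights.
* **The enhancement mask is model-predicted.** A mask chosen by
  thresholding the data selects voxels partly *because* their noise is
  high, which biases the fit. The first pass masks voxels whose 3³
  box-smoothed time-mean increment exceeds `mask_snr` times its noise
  scale; the refit then uses the voxels where the *fitted model* predicts
  an increment above `mask_snr × σ` at some time — a mask independent of
  the noise realisation. At SNR 20 this two-stage scheme recovers D\*
  within ~1% and k′ within a few percent per subject, which the acceptance
  tests verify at all three group parameter sets.

Masks larger than `max_samples` (default 30 000 samples) are thinned
deterministically. Degenerate inputs (all-zero series, fewer than 3 time
frames, fewer than 50 masked samples) raise immediate errors.

**Tortuosity.** λ = √(D_free/D\*), with D_free always reported alongside.
λ < 1 (D\* above the free-medium value) is physically anomalous for a
tortuous medium but can arise — the rotenone group's central values imply
it — so it is permitted and flagged rather than rejected. Note that the
three groups' central (D\*, λ) pairs are not mutually consistent with any
single D_free (they imply 6.74, 4.89 and 4.88 × 10⁻⁴ mm²/s respectively);
the package therefore treats D_free as an explicit configuration parameter
and makes no attempt to resolve the inconsistency.

## Spreading volumes and half-life

A voxel is "lightened" when its increment exceeds `k_sigma × σ` (default
k_sigma = 3; the threshold is always reported with the curve). The volume
curve is the lightened-voxel count times the voxel volume (0.125 mm³ at
0.5 mm), with its maximum `v_max` and time `t_max`.

t½ is estimated from the total-amount curve A(t): log-linear least squares
over the post-peak window (peak onward) gives the decay rate and
t½ = ln 2/rate; an interpolation method (first crossing of half the peak,
log-linearly interpolated) is available and agrees exactly for a pure
exponential. On the analytic model A(t) = Q·e^(−k′t), so the estimator
returns ln 2/k′ — a cross-validation of the fitted k′ that the tests
enforce to 2%.

On *measured* data the whole-grid integral of concentration is useless:
Rician rectification leaves a tiny positive floor on every background
voxel, and ~2.6 × 10⁵ voxels of floor swamp the decaying signal. The
pipeline therefore integrates over the model-predicted enhanced region
only and subtracts the per-time corner-block floor. Even so, early-time
amounts are under-estimated where the signal law saturates near the
source, so the measured t½ is a *descriptive* clearance summary — shorter
than ln 2/k′ under these acquisition settings — rather than a second
estimate of k′. The two are reported side by side for exactly this reason:
on real tissue t½ additionally absorbs bulk ISF outflow, so equality with
ln 2/k′ should not be expected there either.

## Group statistics

Per-subject metrics are summarised as group mean ± SEM and compared by
one-way ANOVA computed explicitly from sums of squares (cross-checked in
the tests against `stats::aov` and a brute-force oracle), followed by the
Student–Newman–Keuls stepwise procedure: group means are ordered, each
contiguous span of p means is tested against
q(1−α; p, df_within)·√(MS_within/n_h) (n_h the harmonic mean group size,
noted when sizes differ), stepping down, and no pair nested inside a span
already declared homogeneous is ever called significant. Studentized-range
quantiles come from `stats::qtukey`; α defaults to 0.05. By construction
SNK sits between the full-span (Tukey-like) criterion and unadjusted
pairwise comparisons — the tests check this sandwich on random fixtures,
and the two-group case reduces exactly to the pooled t-test via
q(2, df) = √2·t.

## What the phantoms do and do not show

The generator reproduces the acquisition geometry and schedule, the
point-source transport physics, T1 signal saturation, Rician noise, and
log-normal between-subject parameter spread. It does **not** contain
anatomy (a uniform baseline), bulk-flow advection, spatially varying D\* or
α, partial-volume effects at tissue boundaries, motion beyond integer-voxel
translation, or scanner drift. Passing recovery tests therefore
demonstrates that the estimation chain is unbiased and well-conditioned
under the model's own assumptions at realistic SNR — not that those
assumptions hold in tissue. The statistics layer is exercised at the
metrics level: per-subject metric values drawn normally around each group's
central values with the groups' dispersions, 10 subjects per group,
confirm that the rotenone-vs-sham differences are detected by ANOVA + SNK
in ≥ 90% of replicates.

## Numerical choices and problem sizes

* Multistart: 4 × 4 log-spaced (D\*, k′) grid; deterministic, so refits are
  reproducible. LM iteration cap 200.
* Sample cap 30 000 per fit; deterministic thinning (every n-th masked
  voxel), never random subsampling.
* Recovery studies in the tests and acceptance script use the full 64³
  grid, the 11-volume schedule and 10 replicates per group; structural
  tests use reduced grids (17³–48³) where the check is scale-free, which
  keeps the default suite around a minute.
* Oracle cross-checks: the closed form is compared against an explicit
  finite-difference evolution of the PDE on a 33³ grid (relative L2
  agreement well under the 5% bound), against hand-frozen values computed
  independently before implementation, and against analytic identities
  (mass conservation, exp(−k′Δt) decay, peak time r²/(6D\*)).
* Ties/degeneracies: ANOVA with zero within-group variance and unequal
  means reports p = 0 and a degenerate flag; SNK with zero standard error
  falls back to exact mean comparison; constant frames register with zero
  shift and a warning; non-decaying amount curves raise "no measurable
  clearance".

## Known limitations

* Bulk flow is not modelled; k′ and t½ conflate clearance routes.
* The registration is integer-voxel and rigid by design; sub-voxel motion
  blurs the source neighbourhood slightly and is not corrected.
* Saturation near the injection site is information lost: no estimator can
  recover early near-source concentrations from a saturated T1 law, which
  is why amplitude and early amounts carry wide uncertainty and the
  measured t½ is descriptive.
* With strongly non-spherical spread (anisotropic tissue), the isotropic
  kernel mis-specifies the field and D\* becomes an orientation average.
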