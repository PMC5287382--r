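# issmri

Tracer-based MRI quantification of brain **interstitial-space (ISS)
microstructure** and **interstitial-fluid (ISF) clearance**.

A gadolinium tracer (Gd-DTPA) micro-injected into deep grey matter (e.g. the
caudate nucleus) spreads through the 38–64 nm wide interstitial space by
hindered diffusion and is cleared from the interstitial fluid. Because
Gd-DTPA shortens the T1 of nearby water, dynamic T1-weighted MRI watches the
tracer cloud spread and fade, and a transport model fitted to those images
yields physiological parameters of the tissue — in health, in disease models
such as rotenone-induced parkinsonism, and under treatment.

`issmri` implements the full analysis chain, plus a phantom simulator so
every stage is testable without animal data:

1. **Simulate** (`generate_phantom_study`) — ground-truth concentration
   fields from the porous-medium point-source diffusion–clearance model,
   mapped to MRI signal and degraded with Rician noise, on the acquisition
   schedule of the motivating experiment (baseline + 0.5, 1, 1.5, 2, 3, 4,
   5, 6, 7, 8 h; 0.5 mm isotropic voxels).
2. **Preprocess** (`register_series`, `subtract_baseline`,
   `signal_to_concentration`) — rigid integer-voxel registration, signal
   increments over baseline, and inversion of the signal law back to tracer
   concentration.
3. **Fit** (`fit_diffusion_model`, `compute_tortuosity`) — joint space–time
   nonlinear least squares for the effective diffusion coefficient D\* and
   clearance rate constant k′; tortuosity λ from D\*.
4. **Summarise** (`spread_volume_timecourse`, `estimate_half_life`,
   `summarize_groups`) — spreading-region volumes, clearance half-life t½,
   and group comparisons by one-way ANOVA with Student–Newman–Keuls (SNK)
   post-hoc tests.

## The model

The interstitial concentration after a point injection of amount *Q* (nmol)
into tissue with ISS volume fraction *α* obeys
∂C/∂t = D\*∇²C − k′C, whose point-source solution is

    C(r, t) = (Q/α) · (4π D* t)^(−3/2) · exp( −r² / (4 D* t) − k′ t )

- **D\*** (mm²/s): effective diffusion coefficient in the ISS, reduced below
  the free-medium value D by structural hindrance;
- **λ = √(D/D\*)**: tortuosity, a geometric hindrance index (≥ 1 in a
  classical porous medium);
- **k′** (1/s): first-order clearance rate of the tracer from the ISF;
- **t½** (min): time for the measured in-brain tracer amount to halve,
  reflecting diffusion, bulk ISF flow and clearance together.

The fit estimates {A = Q/α, D\*, k′, source position} jointly over all
enhanced voxels and time points, evaluating residuals in *signal* space
(where MRI noise is homoscedastic) with a deterministic multistart and a
model-predicted enhancement mask — see the methods vignette
(`vignettes/tracer-iss-quantification.Rmd`) for why.

## Worked example

Simulate one sham-like subject at baseline SNR 20 and recover its
parameters:

```r
library(issmri)

acq  <- acquisition_params()          # TR 1500 ms, TI 900 ms, 0.5-8 h schedule
grid <- voxel_grid()                  # 64^3 voxels, 0.5 mm isotropic

truth <- diffusion_clearance_model(D_star = 2.770e-4, k_prime = 0.648e-4)
scen  <- group_scenario("sham", truth,
                        noise_sigma = snr_to_noise_sigma(acq, 20),
                        n_subjects = 1, seed = 7)
study <- generate_phantom_study(scen, grid, acq)

res <- analyze_subject(study$subjects[[1]], acq)
res$fit
#> <diffusion_fit> D* = 0.000279 mm^2/s  k' = 6.514e-05 /s  A = 100.6 nmol  R^2 = 0.8085 (signal-space)
#>   source at (0.00, -0.01, 0.02) mm; 1669 voxels x 10 times
res$tortuosity$lambda_hat
#> [1] 1.167059
res$half_life$t_half
#> [1] 92.72593
res$spread$v_max
#> [1] 270.375
```

The fitted D\* (2.79 × 10⁻⁴ mm²/s) and k′ (0.651 × 10⁻⁴ /s) recover the
simulated truths (2.770 and 0.648) within about 1%. λ = 1.17 here simply
reflects the default D_free = 3.8 × 10⁻⁴ mm²/s; λ is always reported next to
the D_free used. The measured t½ (92.7 min) is a descriptive quantity: it is
*not* ln 2/k′ because early-time amounts are under-estimated where the T1
signal saturates near the injection site (the vignette discusses this).
v_max is the largest "lightened"-region volume (mm³) across the schedule.

A study-level workflow (simulate → fit → report, NIfTI + CSV + JSON on
disk) is available via `cmd_simulate`, `cmd_fit`, `cmd_report` and the thin
CLI at `inst/cli/issmri.R` with a YAML configuration
(`inst/extdata/demo_config.yaml`).

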