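# llpsfix

Chemical fixation is supposed to preserve what a live cell looked like.
For proteins that form liquid–liquid phase separation (LLPS) condensates,
it often does not: paraformaldehyde cross-linking competes kinetically
with the exchange of molecules in and out of puncta, so fixed-cell images
can over- or under-represent the live-cell condensates. `llpsfix` is an R
package for scientists who quantify condensates in fluorescence
microscopy and want to model, measure, and statistically test this
fixation artifact.

The package implements:

* **A four-state kinetic model of fixation.** A protein exchanges between
  in-puncta (S1) and out-of-puncta (S2) pools with rates k1, k2, and is
  irreversibly cross-linked into fixed pools S3/S4 at rates k3/k4. The
  artifact statistic is

  ΔPP = 100 · S3∞/(S3∞ + S4∞) − 100 · S1₀/(S1₀ + S2₀),

  computed exactly at t = ∞ by a closed-form linear solve (with an ODE
  path for time courses and cross-validation), plus phase-diagram sweeps
  over the k3:k4 ratio and the relative overall fixation rate
  (k3+k4):(k1+k2).
* **LLPS image parameters** on nucleus z-stacks with masks: number of
  puncta (prominence-based find-maxima with a noise tolerance), surface
  roughness (sd of normalised nuclear intensity), and punctate percentage
  (fraction of sum-projection fluorescence inside per-punctum disks of
  diameter equal to the maximum FWHM over 36 radial slices), with
  paired live/fixed percent changes.
* **SPT residence times**: classification of single-molecule trajectories
  by fraction of time in puncta (in: F > 50 %, out: F < 5 %), dwell-time
  survival curves, constrained two-exponential fits
  P(t) = A·exp(−λns·t) + (1−A)·exp(−λs·t), and photobleach correction
  τcorr = 1/(1/τs − 1/τH2B) against an H2B reference, with Wilcoxon
  rank-sum comparisons.
* **Seeded synthetic-data generators** (nucleus stacks with planted
  Gaussian puncta, live/fixed pairs with planted effects, dwell-time
  mixtures with bleaching, labelled trajectory sets) so the whole
  pipeline is testable without microscopy data.

## Worked example

```r
library(llpsfix)

# --- kinetics: 2x faster fixation outside puncta, balanced exchange ---
rs <- rate_set(k1 = 0.15, k2 = 0.15, k3 = 1, k4 = 2)
delta_punctate_percentage(rs)
#> <artifact_result> 50.000% -> 46.939% (delta = -3.061 pp)

# --- images: quantify a synthetic nucleus with 12 planted puncta ---
out <- make_nucleus_stack(synthetic_image_spec(seed = 7))
quantify_puncta(out$stack, out$mask, noise_tolerance = 2e-4)
#> <puncta_quant> 12 puncta; roughness = 3.919e-05; punctate = 8.77%

# --- SPT: recover a 10.23 s residence time through fit + correction ---
spec <- synthetic_dwell_spec(A = 0.5, tau_ns = 2, tau_s = 10.23,
                             tau_bleach = 100, n = 5000, seed = 11)
fit <- fit_two_exponential(survival_curve(make_dwell_times(spec)$dwells))
fit
#> <survival_fit> A = 0.508; tau_ns = 2.01 s; tau_s = 9.33 s (RSS 0.000378)
photobleach_correct(fit$tau_s, 100)$tau_corrected
#> [1] 10.28638
```

Reading the output: with fixation twice as fast outside puncta as inside
(k3 = 1 < k4 = 2), a cell that is 50 % punctate in vivo fixes to 46.9 %
punctate — a −3.06 percentage-point artifact that would read as
"fixation diminishes LLPS". The synthetic nucleus returns exactly its 12
planted puncta, and the apparent 9.33 s specific residence time — shortened
by photobleaching — corrects to 10.29 s against the 100 s H2B reference,
within 0.6 % of the 10.23 s ground truth.

`run_pipeline()` chains all three stages on synthetic data and returns a
long-format study table plus signed-rank / rank-sum summaries; see the
vignette (`vignettes/fixation-artifacts.Rmd`) for the models,
conventions, and design decisions.

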