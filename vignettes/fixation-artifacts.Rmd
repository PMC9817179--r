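---
title: "Quantifying fixation artifacts in LLPS imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fixation artifacts in LLPS imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llpsfix)
```

Aldehyde fixation is routinely assumed to freeze a faithful snapshot of a
living cell. For proteins that undergo liquid–liquid phase separation
(LLPS), that assumption can fail: cross-linking competes kinetically with
the exchange of molecules in and out of condensates, so a fixed cell can
show more, brighter, or fewer puncta than the live cell it came from.
`llpsfix` packages three analyses around this problem — a kinetic model of
the artifact, quantification of LLPS image parameters in paired live/fixed
images, and a residence-time analysis from single-particle tracking (SPT)
— together with seeded synthetic-data generators so every stage can be
exercised and verified without microscopy data.

## The four-state kinetic model

A protein of interest is either in a punctum (S1) or in the dilute
nucleoplasm (S2), exchanging with binding rate $k_1$ (S2→S1) and
dissociation rate $k_2$ (S1→S2). Fixative addition at $t = 0$ opens two
irreversible exits: in-puncta molecules are cross-linked into S3 at rate
$k_3$, out-of-puncta molecules into S4 at rate $k_4$. Mass-action kinetics
give

$$\frac{dS_1}{dt} = k_1 S_2 - (k_2 + k_3) S_1,\qquad
  \frac{dS_2}{dt} = k_2 S_1 - (k_1 + k_4) S_2,$$
$$\frac{dS_3}{dt} = k_3 S_1,\qquad \frac{dS_4}{dt} = k_4 S_2,$$

with total molarity normalised to $S_1+S_2+S_3+S_4 = 1$ mol/L and all
rates in s⁻¹. The artifact statistic is the change in punctate
percentage between the fully fixed end state and the live equilibrium:

$$\Delta PP = 100\,\frac{S_3^\infty}{S_3^\infty + S_4^\infty}
            - 100\,\frac{S_1^0}{S_1^0 + S_2^0}.$$

Two modelling choices matter:

* **Equilibrium starts.** The starting punctate percentage is not an
  independent dial: $k_1$ and $k_2$ define the live equilibrium
  $S_1^{eq}/S_2^{eq} = k_1/k_2$, and the model's zero-artifact laws
  ($\Delta PP = 0$ when $k_3 = k_4$, and at the 0 %/100 % boundaries)
  hold only for starts on that equilibrium. Accordingly
  `delta_punctate_percentage()` defaults `start_pp` to
  `equilibrium_start(rates)`; an explicit off-equilibrium start is allowed
  and documented as modelling a perturbed cell, where these laws need not
  hold.
* **Exact $t=\infty$ instead of long integration.** Because S3/S4 are
  absorbing, the terminal split has a closed form: with the transient
  generator $M$ of (S1, S2) and initial vector $x_0$, the time-integrals
  are $I = (-M)^{-1} x_0$ and $S_3^\infty = k_3 I_1$,
  $S_4^\infty = k_4 I_2$. This avoids any truncation-time choice. The ODE
  path (`simulate_time_course()`, deSolve BDF, rtol $10^{-8}$, atol
  $10^{-10}$) exists for time courses and serves as an independent
  cross-check: terminal states at $t = 50/\min(k_3,k_4)$ agree with the
  closed form to $10^{-6}$ over random rate grids. BDF was chosen over
  lsoda because lsoda's dense-output interpolation fails on the very long
  horizons that slow fixation rates produce; conservation error under BDF
  is at machine precision.

`sweep_phase_diagram()` provides two sweep designs: the in/out
fixation-rate ratio $k_3{:}k_4$ at constant overall rates
($k_3+k_4 = 0.2$, $k_1+k_2 = 1$), and the relative overall fixation rate
$(k_3+k_4){:}(k_1+k_2)$ at constant $k_3 = 1$, $k_4 = 2$. Default grids
are start percentages 0–100 in steps of 2 and 41 log-spaced ratios over
$[10^{-2}, 10^2]$ — wide enough to show both the bifurcating sign
structure (enhancement iff $k_3 > k_4$) and the fast-fixation limit, where
$|\Delta PP|$ falls below 0.1 pp once fixation outpaces exchange a
thousandfold.

```{r kinetics-example}
delta_punctate_percentage(rate_set(k1 = 0.15, k2 = 0.15, k3 = 1, k4 = 2))
```

Degenerate inputs are deliberate choices, not errors: $k_1 = k_2 = 0$
with an explicit interior start means molecules fix in place
($\Delta PP = 0$); $k_3 = k_4 = 0$ is rejected (fixation never
completes); rate sets that strand unfixable mass (e.g. $k_3 = 0$ with
$k_2 = 0$) are rejected as singular.

## LLPS image parameters

Three parameters are measured per nucleus, all defined on z-projections
rather than in 3-D. All intensity images are first
normalised so the summed intensity inside the (user-supplied) nucleus
mask is 1, making live and fixed images comparable and all three
parameters invariant under intensity rescaling.

**Number of puncta** uses ImageJ-style find-maxima semantics, which we
pin down as prominence-based detection: a candidate is an 8-connected
(plateau-aware) local maximum, accepted when its height above the highest
saddle linking it to higher ground inside the mask exceeds the noise
tolerance; maxima merged below tolerance keep the highest peak (ties:
first in row-major order), and plateaus report their rounded centroid.
The implementation is a single descending-intensity union-find sweep with
exact saddles; the test suite checks it pixel-for-pixel against an
exhaustive flood oracle on small images. The noise tolerance has no
published value; it is a required parameter, constrained equal within a
live/fixed pair. Mask-edge maxima are kept by default (`exclude_edge`
opts out).

**Surface roughness** is the standard deviation of normalised intensity
over the mask. The population convention (divide by $N$) is fixed for
determinism; the downstream quantity — percent change between paired
images — is insensitive to the convention.

**Punctate percentage** measures, on the *sum* z-projection, the fraction
of nuclear fluorescence inside punctum disks. Each detected punctum is
refined by slicing 36 diameters (5° steps) through its preliminary
center, sampling by bilinear interpolation at 0.25 px steps to a
half-length of 30 px, and measuring each profile's full width at half
maximum above its own minimum (a local-baseline choice: puncta sit on
nonzero nucleoplasm). The widest slice defines the punctum's FWHM and its
midpoint the refined center — for a clean Gaussian punctum the disk of
diameter FWHM captures exactly half the spot energy, which the tests
exploit ($50\% \pm 2\%$). Disks are clipped to the mask and overlapping
disks count once, so the result cannot exceed 100 %. Profiles that never
fall below half maximum within the window flag the punctum unresolved
(warned, excluded). A limitation worth knowing: for a perfectly isotropic
Gaussian every diameter has the same FWHM, so the "widest slice passes
through the true center" argument only constrains the along-slice
coordinate; real, slightly anisotropic puncta are what make the
refinement informative.

Paired comparison reports, per parameter, the absolute change and the
percent change $100(\text{fixed}-\text{live})/\text{live}$; a zero live
value flags the percent change invalid rather than erroring, and the
per-cell percent changes are averaged and tested (below) rather than
pooled into a change of averages.

## SPT residence times

Slow tracking (500 ms exposures) blurs diffusing molecules, so surviving
tracks are bound molecules and a track's dwell time is its span,
$(\text{last} - \text{first} + 1) \times \Delta t$, with single-frame
tracks dropped. Trajectories are classified against the temporally
nearest puncta mask (masks are acquired every ~10 s): the fraction of
localisations inside puncta, $F$, labels a trajectory in-puncta
($F > 0.5$), out-of-puncta ($F < 0.05$) or ambiguous (retained, excluded
from residence analysis). Only in-puncta trajectories are analysed.

The empirical survival curve $P(t)$ (fraction of dwells $\ge t$) is fit
by constrained least squares to the two-component exponential mixture

$$P(t) = A e^{-\lambda_{ns} t} + (1 - A) e^{-\lambda_s t},$$

with $0 \le A \le 1$ and $\lambda_{ns} \ge \lambda_s > 0$ enforced by
parameterising $\lambda_{ns} = \lambda_s + \delta$, $\delta \ge 0$ — the
fast component is the nonspecific one ($\tau_{ns} = 1/\lambda_{ns}$), the
slow one the specific residence time ($\tau_s = 1/\lambda_s$), and only
$\tau_s$ is carried downstream. (The rates here are conventionally called
k1/k2 in survival analyses; they are renamed to avoid collision with the
kinetic model's binding rates.) The fitter runs Levenberg–Marquardt from
5 log-spaced rate starts spanning the observed dwell range, with a
box-constrained quasi-Newton fallback that is immune to the singular
gradients a degenerate (single-exponential) sample induces; the lowest
residual wins, and a boundary-pinned $A$ is flagged. One numerical
subtlety: frame-quantized dwells are rounded *up* to whole frames, so the
empirical curve at grid time $t$ reflects continuous survival beyond
$t - \Delta t$; the model clock therefore starts at the shortest
observable dwell (`t0 = min(t)`, negligible for continuous data), without
which recovered slow rates are biased low by up to ~15 % at
$\tau_s \approx 10$ s.

Photobleaching makes every observed rate the sum of the true unbinding
rate and the bleach rate. With H2B — effectively immobile on chromatin —
as the session-matched reference, the correction is rate subtraction:

$$\tau_{corrected} = \frac{1}{1/\tau_s - 1/\tau_{H2B}},$$

defined only for $\tau_s < \tau_{H2B}$. Per-cell corrected times are
summarised as mean ± SEM and two conditions are compared by the Wilcoxon
rank-sum test. Dwell censoring at the movie end is not modelled; with the
windows and residence times in scope the truncated mass is negligible,
but the fit is formally uncensored.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their spec (including the seed), and
every fixture carries its ground truth.

* **Nucleus stacks**: an elliptical nucleus with uniform background 10,
  12 Gaussian puncta ($\sigma = 2$ px lateral, $2\sigma$ axial —
  confocal-like anisotropy), amplitude 50, additive Gaussian noise of
  sd 1 (a 50:1 peak-to-noise ratio typical of the bright condensates in
  scope), centers at least 20 px apart inside a 128×128×5 frame. The
  separation constraint (≥ 6σ) is what makes planted counts an exact
  oracle for the detector. Placement is rejection sampling with bounded
  retries; over-packed requests fail with guidance rather than degrading
  the constraint.
* **Live/fixed pairs** re-render the live ground truth with scaled
  punctum count and amplitude and an independent noise draw, recording
  the planted sign of each parameter change (NA when count and amplitude
  pull oppositely).
* **Dwell sets** draw from the two-exponential mixture with bleaching
  composed at the rate level (observed rate = true rate + $1/\tau_b$ —
  exactly the assumption under which the correction formula is exact),
  then quantize up to 0.5 s frames and cap at the observation window.
* **Trajectory sets** plant $F$ exactly (1, 0, or 0.3 per class) by
  sampling localisations from each frame's temporally nearest mask.

What passing tests on these fixtures shows is that the estimators are
correct under their own assumptions: Gaussian spots, additive Gaussian
read noise, exponential mixtures, masks that are right. Real microscopy
adds shot noise, aberrated and overlapping spots, hand-drawn mask error
and tracking mistakes, none of which the fixtures emulate — so green
tests here validate the computation, not the microscope.

## Statistics

Paired live/fixed parameter changes use the Wilcoxon signed-rank test
(zeros dropped, exact for $n \le 25$ without ties, normal approximation
with continuity correction otherwise); condition comparisons use the
rank-sum test with the same conventions — both delegated to
`stats::wilcox.test` and verified against brute-force enumeration in the
tests. The significance threshold is surfaced as configuration (default
0.05).

## Problem sizes and reproducibility

The shipped test and pipeline configurations use sizes chosen to keep a
full run interactive while leaving estimator error well inside the
asserted tolerances: phase diagrams on 51×41 grids, oracle cross-checks
on 100 random rate sets, detector oracles on ≤ 24×24 images, residence
recovery at 5000 dwells per fit, and 200-replicate type-I-error studies.
`run_pipeline()` records seed, configuration and package version in its
provenance block, and identical configurations reproduce identical study
tables bit for bit. `scripts/acceptance.R` recomputes the headline
quantities (kinetic limits, conservation, residence-time recovery) from
scratch for any seed.
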