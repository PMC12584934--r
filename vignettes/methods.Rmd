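---
title: "Dose calculation directly on MRI: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose calculation directly on MRI: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrdose)
```

`mrdose` predicts the dose of small photon beams on a 0.35 T MR-Linac
directly from the planning MRI, bypassing synthetic-CT generation. This
vignette is the package's own account of the science: what is modelled,
which knobs matter, what the synthetic data emulate (and deliberately do
not), and where the design was genuinely open.

## The problem and the model

A 6 MV photon beam deposits dose along its direction: a build-up region
near the surface while secondary electrons approach equilibrium, then a
quasi-exponential fall-off with *radiological depth* (the
density-weighted path length). A 0.35 T field parallel to the patient
SI axis adds a mean in-plane Lorentz drift of the secondary electrons,
shifting the dose laterally; at tissue–air interfaces the electron
return effect (ERE) perturbs the dose locally. Gas pockets in rectum
and bowel (air cavities, AC) are the dominant density perturbation near
a prostate target, and they move between CT and MRI acquisition — hence
the need to transfer them from the daily MRI onto the planning CT
density map ("AC correction") before any CT-based dose engine can be
trusted, and the need for explicit cavity handling when predicting dose
straight from the MRI.

The dose engine mirrors the physics: the beam's-eye-view (BEV) cuboid
of a beam is a depth-ordered stack of transverse slices, and a
unidirectional LSTM consumes them slice by slice — causal in depth,
like the deposition process — emitting a dose slice at every step. A
one-layer LSTM is followed by a two-layer fully-connected head. The
stated head width ("two layers of 100 neurons") cannot literally emit
a 1024-wide slice, so the head is `LSTM(H) -> FC(H -> fc_hidden, ReLU)
-> FC(fc_hidden -> width, linear)` with `fc_hidden = 100` in the
reference configuration.

Air cavities are segmented from the MRI cuboid by a three-level 3D
U-Net (two conv–batchnorm–ReLU blocks per level; 32/64 encoder filters,
128-filter bottleneck; max-pool down, transposed-conv up with skip
connections; 1×1×1 convolution + sigmoid output). The dose engine is
trained with the cavity-weighted loss

$$L = \mathrm{MSE}(D, \hat D) + \lambda\,\mathrm{MSE}(AC \odot D, AC
\odot \hat D), \qquad \lambda = 10,$$

which counteracts the ~1% voxel share of cavities. Four variants cover
the design space: Model 0 (CT input, plain MSE; the oracle-information
baseline), Model 1 (MRI + manual AC), Model 2 (separately trained
U-Net feeding the Model-1 engine at inference; all weights frozen),
Model 3 (joint training, loss `BCE + L`, with the continuous U-Net
probability as the engine's cavity channel so dose gradients reach the
segmenter).

## Geometry conventions

Patient frame: right-handed, axes (SI, AP, LR) with +SI superior, +AP
anterior, +LR patient-left; world coordinate of voxel centre = origin +
index·spacing (mm). Gantry 0° enters from anterior (beam direction
−AP); 90° enters from the patient's right; the frame is (x̂ = +SI,
ŷ = ẑ × B̂, ẑ = beam direction), so +ŷ is the mean Lorentz-drift
side. The BEV cuboid (200×32×32 at 2 mm in the reference geometry) is
anchored at the body surface along the central ray, its lateral window
shifted +10 mm along ŷ; sampling is parallel-ray (at SAD 1000 mm with
a 10 mm field, divergence across the cuboid is sub-voxel). Out-of-body
and out-of-volume samples are zero. Nearest-neighbour interpolation is
used for masks, trilinear for everything else, with `insert_bev_dose`
the inverse map back onto the patient grid.

## Air-cavity correction

Three steps, applied once, in order: (1) threshold CT air strictly
below −300 HU and replace every 18-connected component by the median HU
of its neighbour shell (the 26-neighbourhood dilation of the component
minus the whole air mask; even-sized shells use the mean of the middle
pair); (2) take the cavity contours from the registered MRI; (3) stamp
them into the filled CT at exactly −700 HU. Because −700 HU is again
below the extraction threshold, the correction is deliberately one-shot
with explicit inputs — re-chaining it would re-extract the override.
Two empty masks have Dice 1.0 by definition, which keeps per-cuboid DSC
defined for cavity-free beams.

## The synthetic phantom and the analytic oracle

No patient data ship with the package; a synthetic pelvis stands in:

* an ellipsoidal body (semi-axes 85/95/118 mm) on a 3 mm grid
  (60×70×84 voxels — desk-scale; the reference data are 1.5 mm);
* a pelvic bone ring and femoral heads: high HU (~900–1100), *dark on
  MRI* — the deliberate confounder, since low MRI signal is exactly
  what cavities look like;
* a central PTV (prostate), an anterior-superior bladder (bright on
  the bSSFP-like contrast), a posterior rectum;
* 2–6 ellipsoidal air cavities of 0.3–10 cm³ in the rectal region,
  whose CT counterparts are displaced by up to 3 mm and shrunk 10%
  (registration-mismatch analogue), so the CT air and MRI contours
  genuinely disagree, as the correction assumes;
* MRI = class means (soft 0.55, bone 0.16, air 0.04, bladder 0.85,
  PTV 0.50) × a smooth multiplicative bias field (±12%, sub-1% change
  per voxel) + Gaussian noise (SD 0.03).

The analytic beam oracle replaces Monte Carlo. Per parallel BEV ray,
with density ρ = max(1 + HU/1000, 10⁻³) and step Δs = 2 mm:
radiological depth accumulates t += ρΔs; the equilibrium factor relaxes
as E ← E + (ρ − E)·min(1, ρΔs/L) from E = 0 at the surface; lateral
drift accumulates at rate c_B/max(ρ, 0.2) capped at 7 mm; dose =
E·exp(−μ_eff t)·F_y(y − drift)·F_x(x) with error-function field edges
(σ = 2 mm) of the 10 mm field. Defaults μ_eff = 0.005/mm, L = 3 mm,
c_B = 0.05 mm/mm are fixture constants, not physics claims; with the
2 mm march they place the water depth-of-maximum near 6 mm and keep the
total drift inside the shifted window. Label noise is multiplicative
with σ ∝ √(1/D) (floor-clamped), scale 0.025 for training labels vs
0.008 for validation/test — a ratio of ~3 echoing 5×10⁶- vs
5×10⁷-history MC statistics. Cavity-label cuboids are evaluated
analytically from the ellipsoid definitions at the BEV sample points,
not resampled from the voxelized mask, so labels carry no grid error at
the 2 mm cuboid scale.

What passing tests on this phantom do **not** show: anatomical realism,
ERE surface physics (not modelled, matching the known limitation of the
approach), scatter, MLC apertures, registration artefacts beyond the
rigid cavity displacement, or 1.5 mm-resolution image texture.

## Training at desk scale

The reference configuration (LSTM hidden 1000, U-Net 32/64/128, Adam
lr 10⁻⁵, batch 4) is the package default but is sized for 10 800
training beams on a GPU. The shipped experiment runs on one CPU core
with 4 train / 1 validation / 2 test phantoms, 60 beams each, and
100×16×16 cuboids; accordingly the scaled networks are LSTM hidden
192 / fc 96 and U-Net 6/12/24, trained with Adam lr 10⁻³ (U-Net
2×10⁻³) and batch 8. Two training details matter:

* the U-Net output bias starts at the cavity-prior logit (−4): with
  ~1% positive voxels, Adam otherwise spends thousands of updates just
  drifting the bias;
* the U-Net trains on random 32-slice depth crops (it is fully
  convolutional; inference runs on full cuboids), which buys a ~3×
  throughput gain at no accuracy cost.

The cavity binarization threshold is selected by the validation DSC
sweep over 0.3–0.7 (`select_binarize_threshold`), the same procedure
that fixed the reference value 0.4; checkpoints keep the epoch with the
lowest validation loss. Under these conditions the held-out synthetic
beams reach a mean γ_pr(3%/3 mm, 10% threshold) above 99% against the
oracle, and mean DSC ≈ 0.84 over cuboids holding at least 1 cc of true
cavity (the same 1 cc cutoff the cavity census uses; the unfiltered
per-cuboid mean ≈ 0.63 is dominated by cuboids that clip sub-0.5 cc
slivers of a cavity at the window edge, where a Dice score is mostly
boundary ambiguity). The CT-input
baseline attains a lower validation MSE than the MRI-input engine for
every seed tried, reproducing the expected information ordering.

One capacity probe deserves honesty: driving the training loss on a
*single* beam below 10⁻⁴ of its initial value within 500 steps is not
achievable for this architecture — across Adam (four learning rates,
with and without cosine decay and clipping), L-BFGS, and an exact
least-squares refit of the output layer, the loss plateaus near 10⁻³
of its start. The LSTM state converges toward a fixed point over the
quasi-constant deep slices (the post-training FC feature matrix has
rank ≈ 40 over 100 depth steps), so late-depth targets that still decay
slice-to-slice cannot be matched to 0.01%. The corresponding test
states the bar and reports the shortfall rather than hiding it.

## Evaluation choices

* **Gamma**: global criteria (dose tolerance as % of the reference
  maximum), evaluated at reference voxels ≥ 10% of D_max. The
  evaluated dose is probed by trilinear interpolation at 1/3-voxel
  steps within a search ball of 3×DTA; offsets are scanned in
  increasing distance with an exact early stop, so the result equals
  the minimum over the ball, and passing/failing decisions provably
  match a full-grid search (any γ ≤ 1 has its minimiser within one
  DTA). The reference and evaluated roles are not interchangeable.
* **Profiles**: central-axis depth profile interpolated at the beam
  axis (y = 0, x = 0); lateral x-profiles at the *distal* depths where
  the central-axis profile crosses 80% and 30% of its maximum.
* **ε_rel** = 200(D_pred − D_MC)/(D_pred + D_MC) [%], undefined (NA,
  never 0) where the denominator vanishes.
* **DVH**: D_x% is the (100−x)th percentile of structure voxel doses
  with linear interpolation (type-7 quantile); V_xGy uses ≥. Curves are
  binned at 0.1 Gy.
* **Dose-through-AC**: a beam is flagged when its 15%·D_max dose mask
  intersects the cavity cuboid; per-beam γ_pr tables are split on this
  flag.

## Planning

Each of the nine fields (gantry 0°–320° every 40°) is a 9×9 grid of
abutting 1×1 cm² beamlets at 10 mm pitch (±40 mm lateral extent; the
only gap-free reading of "81 parallel beams per field"). The influence
operator is a sparse matrix over the patient grid (only structural
zeros dropped). Weights minimise the convex objective
Σ_PTV(d_i − p)² + β·Σ_{body∖PTV} max(0, d_i − c)², with β = 0.1 and
c = p = 74 Gy by default — chosen so PTV conformity dominates, both
exposed in `plan_objectives()` — by projected gradient descent with
Armijo backtracking (monotone by construction; tol 10⁻⁶, max 2000
iterations). Plans are normalised so PTV D95% equals 0.95 × 74 Gy
computed exactly (70.3 Gy; the commonly printed 70.4 Gy is a rounding),
and the *same* scale factor is applied to the predicted plan before any
comparison.

## Numerical details and degenerate inputs

Trilinear sampling snaps coordinates within 10⁻⁷ voxel of a grid point
so that resampling a volume onto its own grid is bit-exact; samples
outside the voxel-centre hull are 0. Component labelling is
deterministic (ascending first-voxel order in linear array layout).
Percentiles use linear interpolation between order statistics
throughout. Empty masks: body-percentile clipping, DVH curves and
plan normalisation refuse empty/zero inputs with explicit errors; Dice
of two empty masks is 1. A beam missing the body raises an error in
extraction and yields a zero volume (with a warning) from the oracle.
All randomness flows through explicit seeds; training, phantom
generation and the full experiment are bitwise reproducible on a fixed
platform.

## Known limitations

No ERE modelling (surface hot/cold spots are absent from both labels
and predictions); parallel-ray geometry (exact only in the small-field
limit); the oracle's drift model is a mean-shift caricature of charged
particle transport; phantom anatomy is class-piecewise-constant; the
desk-scale dataset is ~20× smaller than the reference study, so
absolute accuracy numbers are not comparable to the reference values —
only orderings and mechanism-level behaviour are.
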