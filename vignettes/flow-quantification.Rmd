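---
title: "Quantifying craniospinal CSF and cerebral blood dynamics from cine phase-contrast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying craniospinal CSF and cerebral blood dynamics from cine phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpulse)
```

## The physiological problem

Each cardiac systole pushes a bolus of arterial blood into the rigid
cranium. Because intracranial contents are incompressible, that volume
must be bought back within the same cycle: immediately and partially by
cerebrospinal fluid (CSF) flushing through the foramen magnum into the
spinal subarachnoid space ("mobile compliance"), and later and completely
by increased venous outflow. Over the full cycle the mean intracranial
volume is conserved (the Monro–Kellie regime), but instantaneously the
balance fails by a small amount — the intracranial volume change (IVC) —
which drives the intracranial pressure pulse. In Chiari malformation the
cerebellar tonsils crowd the foramen magnum and restrict the CSF route;
this package quantifies every term of that balance from cardiac-gated
phase-contrast MRI (PC-MRI) and reproduces the two-group cohort analysis
(patients with versus without an associated syrinx).

## From velocity images to flow curves

A PC-MRI acquisition encodes through-plane velocity into image phase, one
2D slice per compartment, gated into **32 cardiac phases**. Signed
velocity is linear in the stored phase code up to the encoding limit
(`venc`): `phase_to_velocity()` applies `v = code / code_range * venc`.
Velocities beyond `venc` wrap by `2*venc`; `unwrap_aliasing()` undoes
single wraps by detecting per-pixel temporal jumps larger than `venc`.
The compartment-specific limits are 60 cm/s for blood, 10 cm/s for
aqueductal CSF, 5 cm/s for other CSF (including syrinx fluid) and 2 cm/s
for tonsil tissue motion, with 0.6 × 0.6 mm pixels; a pixel wrapped at
*every* phase shows no jump and is left unchanged (flagged by the
correction count). An optional `background_offset_correct()` removes an
eddy-current-like baseline, estimated as the median temporal-mean
velocity over a static-tissue mask; it is off by default since the
upstream reconstruction may already have dealt with it.

Regions of interest are delineated semi-automatically by
`segment_pulsatile()`: the operator supplies one seed pixel; the
algorithm averages a reference waveform over the seed's 3×3
neighbourhood and keeps pixels whose temporal waveform exceeds a noise
floor in standard deviation **and** correlates with the reference at
`|r| >= 0.7` (absolute value, so counter-phase flow in the same plane
qualifies), returning the 8-connected component containing the seed.
The noise floor defaults to 3× the median temporal SD of the grid-border
pixels. Raising the threshold can only shrink the mask, and the whole
procedure is deterministic. The published pipeline names no specific
algorithm for its semi-automatic step; correlation-with-reference
thresholding is this package's concrete realisation of that contract.

`compute_flow_curve()` then multiplies ROI area by velocity:
`Q_k = sum over ROI of v(px, k) * A_px`, giving a 32-sample volumetric
waveform in mL/s.

## Derived quantities

* **Stroke volume** (`stroke_volume()`): with `V+` and `V-` the
  trapezoidal integrals (periodic closure over the 32 uniform samples) of
  the positive and negative flow, `SV = (V+ + V-)/2` in µL per cardiac
  cycle — the one-directional displaced volume for a pure oscillation,
  robust to a small physiological net flow. CSF and tissue curves are
  *not* detrended before integration; the arteriovenous curve is.
* **Peak amplitude** (`peak_amplitude()`): `max - min` of the curve.
* **CBFa** (`cerebral_arterial_flow()`): sum of both internal carotid
  and the basilar artery curves; its temporal mean in mL/min.
* **CBFv** (`cerebral_venous_flow()`): sum of straight and superior
  sagittal sinus curves.
* **α factor** (`alpha_factor()`): `mean(CBFa)/mean(CBFv)`. The sinuses
  do not drain everything; α = 1 means exclusive sinus drainage and
  `sinus_participation()` = 100/α gives the sinus share in percent
  (α = 2 → 50%). Values below 1 are flagged with a warning, not
  rejected.
* **Corrected venous curve and arteriovenous curve**:
  `corrected_CBFv = α * CBFv` equalises the means, so
  `AV = CBFa − corrected_CBFv` has zero temporal mean by construction
  (asserted to 1e-9 relative). Its detrended stroke volume is
  **SV_blood** (mL/CC), and its running trapezoidal integral is the
  **IVC curve**, which closes to zero over the cycle.

α is computed from full-cycle temporal means, not systolic windows, and
units follow the study convention: CBF in mL/min, CSF stroke volumes in
µL/CC, SV_blood in mL/CC.

## What the synthetic data emulate

No patient data accompany the study, so the package generates its own
test substrate with known ground truth at the acquisition geometry above.

`make_velocity_series()` embeds a pulsatile ROI (disc, annulus, or
several discs) in a static background. In-ROI pixels carry the prescribed
total-flow waveform divided by ROI area — plug flow by default, which
makes the ground-truth stroke volume *exactly* the waveform's integral; a
parabolic profile is available for disc ROIs to exercise segmentation
against spatial velocity gradients (for annuli the cross-gap profile is
underdetermined, so they stay uniform). Waveform shapes are a sinusoid,
a gamma-variate arterial pulse, and an asymmetric biphasic CSF
oscillation; each is normalised to zero mean and peak-to-trough
`2*amplitude`, and the 32 discrete samples are re-centred so the sample
mean equals `mean_offset` exactly — prescribed mean flows are therefore
exact inputs. Noise is additive Gaussian on velocity by default (no noise
model is published); a phase-noise option perturbs the encoding phasor
instead, giving Rician magnitude statistics. Aliasing, when enabled,
wraps velocities modulo `2*venc` exactly as the reconstruction would.
The cycle duration defaults to 1 s (60 bpm); the study gated by finger
plethysmograph but reports no heart rates. What these phantoms do *not*
emulate: k-space sampling, partial-volume edges, eddy-current fields or
motion — so passing recovery tests demonstrates correctness of the
quantification chain, not robustness to every scanner artefact.

`make_cohort()` draws per-subject metric vectors per group from a
multivariate normal at the published group means and SDs, with the
published pairwise correlations as hard targets. Pairs without a
published value default to zero correlation — an explicit assumption.
The resulting target matrix is not positive semidefinite, so it is
completed by alternating projections that hold every *specified* entry
fixed and move only the defaulted entries; if the specified targets
themselves cannot be realised within `repair_tol` (default 0.02) the
generator refuses and names the worst pair. (A plain nearest-PSD repair
would drag the strongest published correlation, α vs cervical CSF SV in
the syrinx group, from −0.80 to about −0.67, defeating parameter
recovery; holding specified entries fixed is the only repair consistent
with reproducing the published values.) Draws are truncated at zero by
resampling whole subjects rather than clipping, which preserves the
correlation structure to first order; the price is a small conditioning
bias — metrics whose mean sits below ~2 SD of zero (e.g. the aqueductal
SV at 47 ± 35) gain a few percent of mean, and recovered correlations
shift by ≲0.01 from their targets at n = 5000. The syrinx SV exists only
in the with-syrinx group and is `NA` elsewhere.

## Statistical layer

`compare_groups()` applies a two-sided Mann–Whitney test per metric
(exact when the smaller group has ≤ 20 subjects and no ties, normal
approximation with tie correction otherwise); Student's t (Welch) is
available because the study's table caption cites it while its methods
text names Mann–Whitney — when the two disagree on significance both
should be reported. No multiple-testing correction is applied, matching
the study's analysis. `correlate()` returns the signed Pearson r, its
two-sided p, and the OLS slope and intercept of y on x, per group or
overall; the published correlation tables print these under an "R²"
header, but the negative entries identify them as signed r, and that is
how the package labels them. `build_tables()` renders the three
publication-style tables (mean ± SD columns with "/" placeholders for
one-group metrics, and "r (p)" cells).

## Numerical choices and problem sizes

Trapezoidal integration on the 32 uniform samples with periodic closure
is used throughout, without spline upsampling: for a sinusoid the
32-sample stroke volume is within 0.35% of the closed form `A·T/π`, well
inside the 5% recovery bands used in testing. Ties at the segmentation
threshold are included; connectivity is 8-neighbour. The test suite and
the acceptance script run on single planes of 40–64 px squared (a few
hundred ROI pixels) and cohorts of 5000 per group for correlation
recovery — sizes at which recovery estimates have standard errors an
order of magnitude below the tolerances being checked, while the whole
suite completes in seconds.

## Known limitations

* Single-wrap temporal unwrapping only; a compartment measured at less
  than half its true peak velocity needs a repeat acquisition, not this
  correction.
* The α factor is a drainage-repartition proxy; accessory (epidural)
  veins are never measured directly here, as in the study.
* Arteriovenous peak-delay (latency) analysis is out of scope.
* The cohort generator reproduces first- and second-order structure
  (means, SDs, targeted correlations) — not distributional shape,
  measurement error, or any longitudinal structure of real cohorts.
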