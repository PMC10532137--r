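# csfpulse

Quantification of craniospinal cerebrospinal-fluid (CSF) and cerebral
blood dynamics from cardiac-gated (cine) phase-contrast MRI, for
researchers studying intracranial compliance — in particular Chiari
malformation with or without an associated syrinx.

Every cardiac systole drives arterial blood into the rigid cranium; CSF
flushing through the foramen magnum and delayed venous outflow must buy
that volume back within the cycle. `csfpulse` computes each term of this
balance from 32-phase velocity image series and runs the two-group cohort
statistics on the resulting per-subject metrics:

* **Flow curves** `Q_k = Σ_ROI v(px, k) · A_px` (mL/s, 32 cardiac
  phases), from semi-automatic, seed-based segmentation of the pulsatile
  region.
* **Stroke volume** `SV = (V⁺ + V⁻)/2` with `V± = ∫ max(±Q, 0) dt`
  (µL per cardiac cycle), for the aqueduct, foramen magnum, prepontine
  cistern, cervical subarachnoid space, tonsils and syrinx.
* **CBFa** = mean of (left ICA + right ICA + basilar) flow;
  **CBFv** = mean of (straight + superior sagittal sinus) flow (mL/min).
* **α factor** = mean(CBFa)/mean(CBFv), the venous drainage repartition:
  α = 1 is exclusive sinus drainage and the sinus share of total
  drainage is 100/α % (α = 2 → 50%).
* **corrected_CBFv** = α · CBFv, the **arteriovenous curve**
  CBFa − corrected_CBFv (zero mean by construction), its stroke volume
  **SV_blood** (mL/CC) and its running integral, the intracranial
  volume change **IVC(t)**.
* **Cohort layer**: Mann–Whitney group comparison (Student's t as
  cross-check), Pearson correlation + linear regression per group and
  overall, publication-style tables.

Because the underlying patient images are not public, the package ships
a first-class synthetic-data module: velocity-image phantoms with exact
ground-truth flow (arbitrary waveforms, plug or parabolic profiles,
Gaussian or phase/Rician noise, venc aliasing) and two-group subject
cohorts with prescribed means, SDs and pairwise correlation structure.

## Worked example

The `analysis/` scripts form a complete workflow. Steps 01–02 simulate
one subject's full exam (11 planes, NIfTI + JSON sidecars) and quantify
it back through segmentation and flow integration:

```sh
Rscript analysis/01_simulate_subject.R
Rscript analysis/02_flow_metrics.R
```

```
csf_cerv           ROI  332 px  SV  587.3 uL (truth  587.0)
syrinx             ROI   81 px  SV   46.9 uL (truth   47.0)
CBFa 728.0 mL/min, CBFv 498.6 mL/min, alpha 1.460 (sinus participation 68.5%)
SV_blood 0.802 mL/CC, IVC peak-to-trough 0.797 mL
```

Reading: the cervical CSF stroke volume is recovered within 0.1% of its
prescribed truth; the arterial mean of 728 mL/min against a sinus mean of
498.6 mL/min gives α = 1.46, i.e. the sinuses carry 68.5% of cerebral
drainage; roughly 0.8 mL of blood oscillates in and out of the cranium
each cycle. Steps 03–05 generate the 9/19 two-group cohort and reproduce
the statistical tables (`results/tables/`), e.g. the strong negative
coupling between venous repartition and cervical CSF pulsatility in the
syrinx group:

```
alpha vs SV_CSF-cerv (syrinx group, n = 9): r = -0.61 (p = 0.079), slope = -363.6 uL per unit alpha
```

In code, the core calls are:

```r
library(csfpulse)
sim <- make_velocity_series(
  plane_spec(grid_size = 64, pixel_mm = 0.6, venc = 5,
             roi = list(type = "annulus", center = c(32, 32),
                        r_inner_mm = 5, r_outer_mm = 8)),
  calibrate_stroke_volume(
    make_waveform(waveform_spec("biphasic_csf", amplitude = 1)), 587))
seg <- segment_pulsatile(sim$series, seed = c(32, 43), threshold = 0.7)
stroke_volume(compute_flow_curve(sim$series, seg))
#> [1] 587
```

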