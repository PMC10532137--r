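#!/usr/bin/env Rscript
# Simulate one subject's complete craniospinal phase-contrast exam with
# known ground truth: three arterial planes (both internal carotids +
# basilar), two venous sinus planes, and the five CSF/tissue planes
# (aqueduct, foramen magnum CSF, tonsils, prepontine cistern, cervical
# SAS) plus a syrinx plane. Ground-truth stroke volumes and mean flows are
# prescribed to the with-syrinx cohort means; images go to scratch/planes/
# as NIfTI + JSON sidecars with a subject manifest for step 02.

library(csfpulse)

out_dir <- "scratch/planes"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260928L

disc <- function(c, r) list(type = "disc", center = c, radius_mm = r)
ann <- function(c, ri, ro) list(type = "annulus", center = c,
                                r_inner_mm = ri, r_outer_mm = ro)

csf_wave <- function(sv_ul) calibrate_stroke_volume(
  make_waveform(waveform_spec("biphasic_csf", amplitude = 1)), sv_ul)
# pulsatility (amplitude/mean) 0.6 for arteries; the venous pulse is
# damped (0.5) and delayed by 5% of the cycle, giving an arteriovenous
# stroke volume on the published scale (~0.8 mL/CC)
vessel_wave <- function(mean_ml_min, phase = 0, pulsatility = 0.6)
  waveform_spec("arterial_like",
                amplitude = pulsatility * mean_ml_min / 60,
                mean_offset = mean_ml_min / 60, phase_shift = phase)

# per-plane protocol: compartment-specific venc, 0.6 mm pixels, geometry
# sized to keep peak velocities inside the encoding range
cbfa_target <- 728                       # mL/min, arterial total
cbfv_target <- cbfa_target / 1.46        # sinus drainage at alpha = 1.46
planes <- list(
  left_carotid  = list(venc = 60, roi = disc(c(20, 20), 3), grid = 40,
                       wf = vessel_wave(290), seed_px = c(20, 20)),
  right_carotid = list(venc = 60, roi = disc(c(20, 20), 3), grid = 40,
                       wf = vessel_wave(290), seed_px = c(20, 20)),
  basilar       = list(venc = 60, roi = disc(c(20, 20), 2.5), grid = 40,
                       wf = vessel_wave(148), seed_px = c(20, 20)),
  straight_sinus    = list(venc = 60, roi = disc(c(20, 20), 2.5),
                           grid = 40,
                           wf = vessel_wave(cbfv_target / 3, phase = 0.05,
                                            pulsatility = 0.5),
                           seed_px = c(20, 20)),
  superior_sagittal = list(venc = 60, roi = disc(c(20, 20), 4), grid = 40,
                           wf = vessel_wave(2 * cbfv_target / 3,
                                            phase = 0.05,
                                            pulsatility = 0.5),
                           seed_px = c(20, 20)),
  aqueduct   = list(venc = 10, roi = disc(c(24, 24), 2), grid = 48,
                    wf = csf_wave(47), seed_px = c(24, 24)),
  csf_fm     = list(venc = 5, roi = ann(c(32, 32), 8, 12), grid = 64,
                    wf = csf_wave(484), seed_px = c(32, 49)),
  tonsils    = list(venc = 2, roi = disc(c(32, 32), 6), grid = 64,
                    wf = csf_wave(181), seed_px = c(32, 32)),
  csf_ppc    = list(venc = 5, roi = disc(c(24, 24), 4), grid = 48,
                    wf = csf_wave(365), seed_px = c(24, 24)),
  csf_cerv   = list(venc = 5, roi = ann(c(32, 32), 5, 8), grid = 64,
                    wf = csf_wave(587), seed_px = c(32, 43)),
  syrinx     = list(venc = 5, roi = disc(c(24, 24), 3), grid = 48,
                    wf = csf_wave(47), seed_px = c(24, 24)))

manifest <- list()
for (i in seq_along(planes)) {
  nm <- names(planes)[i]
  p <- planes[[nm]]
  pl <- plane_spec(grid_size = p$grid, pixel_mm = 0.6, venc = p$venc,
                   roi = p$roi, noise_sd = 0.05, seed = seed + i)
  sim <- make_velocity_series(pl, p$wf, compartment = nm)
  path <- file.path(out_dir, paste0(nm, ".nii.gz"))
  write_velocity_series(sim$series, path)
  write_roi_mask(sim$truth_mask, file.path(out_dir,
                                           paste0(nm, "_truth.nii.gz")))
  manifest[[nm]] <- list(image = path, seed_px = p$seed_px,
                         truth_sv_ul = sim$truth_sv_ul,
                         truth_mean_flow_ml_min = sim$truth_mean_flow_ml_min)
  message(sprintf("%-18s venc %2g  truth SV %6.1f uL  mean %6.1f mL/min",
                  nm, p$venc, sim$truth_sv_ul,
                  sim$truth_mean_flow_ml_min))
}
jsonlite::write_json(manifest, file.path(out_dir, "subject_manifest.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", length(planes), " planes + manifest to ", out_dir)
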