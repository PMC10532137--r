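# Shared builders for synthetic acquisitions used across test files.

# cervical-like CSF plane: annular oscillatory region, 0.6 mm pixels,
# venc 5 cm/s, ground-truth stroke volume prescribed in uL
cervical_plane <- function(sv_ul = 587, noise_sd = 0, seed = 101,
                           aliasing = FALSE) {
  pl <- plane_spec(grid_size = 64, pixel_mm = 0.6, venc = 5,
                   roi = list(type = "annulus", center = c(32, 32),
                              r_inner_mm = 5, r_outer_mm = 8),
                   noise_sd = noise_sd, aliasing = aliasing, seed = seed)
  wf <- make_waveform(waveform_spec("biphasic_csf", amplitude = 1,
                                    period = 1),
                      compartment = "csf_cervical")
  make_velocity_series(pl, calibrate_stroke_volume(wf, sv_ul),
                       compartment = "csf_cervical")
}

# small arterial plane (disc) with prescribed mean flow in mL/min
arterial_plane <- function(mean_ml_min, radius_mm = 3, seed = 202,
                           center = c(20, 20), grid = 40,
                           phase_shift = 0) {
  pl <- plane_spec(grid_size = grid, pixel_mm = 0.6, venc = 60,
                   roi = list(type = "disc", center = center,
                              radius_mm = radius_mm),
                   noise_sd = 0, seed = seed)
  wf <- waveform_spec("arterial_like", amplitude = mean_ml_min / 60 * 0.6,
                      mean_offset = mean_ml_min / 60, period = 1,
                      phase_shift = phase_shift)
  make_velocity_series(pl, wf, compartment = "arterial")
}

# a pulsatile disc plane for segmentation tests
disc_plane <- function(noise_sd = 0, seed = 303, radius_mm = 4,
                       amplitude = 1.5, grid = 64) {
  pl <- plane_spec(grid_size = grid, pixel_mm = 0.6, venc = 10,
                   roi = list(type = "disc", center = c(grid / 2, grid / 2),
                              radius_mm = radius_mm),
                   noise_sd = noise_sd, seed = seed)
  wf <- waveform_spec("sinusoid", amplitude = amplitude, period = 1)
  make_velocity_series(pl, wf, compartment = "test_disc")
}

# peak in-ROI velocity (cm/s) of a noise-free generated plane
peak_roi_velocity <- function(sim) {
  max(abs(sim$series$v[rep(sim$truth_mask$mask, 32)]))
}
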