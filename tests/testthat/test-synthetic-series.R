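test_that("noise-free construction reproduces the prescribed flow exactly", {
  sim <- cervical_plane(sv_ul = 500)
  fc <- compute_flow_curve(sim$series, sim$truth_mask)
  expect_equal(fc$values, sim$truth_curve$values, tolerance = 1e-10)
  expect_equal(stroke_volume(fc), 500, tolerance = 1e-8)
})

test_that("reported ground truth equals the waveform's own stroke volume", {
  wf <- waveform_spec("biphasic_csf", amplitude = 1.4)
  pl <- plane_spec(grid_size = 48, venc = 5,
                   roi = list(type = "disc", center = c(24, 24),
                              radius_mm = 4))
  sim <- make_velocity_series(pl, wf)
  expect_identical(sim$truth_sv_ul, stroke_volume(make_waveform(wf)))
  expect_identical(sim$truth_mean_flow_ml_min,
                   mean_flow(make_waveform(wf), "ml_min"))
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- cervical_plane(noise_sd = 0.3, seed = 99)
  b <- cervical_plane(noise_sd = 0.3, seed = 99)
  c <- cervical_plane(noise_sd = 0.3, seed = 100)
  expect_identical(a$series$v, b$series$v)
  expect_false(identical(a$series$v, c$series$v))
})

test_that("velocities beyond venc wrap modulo 2*venc when aliasing is on", {
  # disc whose uniform in-ROI velocity peaks at 7 cm/s with venc 5
  pl <- plane_spec(grid_size = 32, pixel_mm = 1, venc = 5,
                   roi = list(type = "disc", center = c(16, 16),
                              radius_mm = 3), aliasing = TRUE)
  # build flow so that the uniform in-ROI velocity is exactly 7*sin
  mask <- csfpulse:::.resolve_roi(pl)$union
  area_cm2 <- sum(mask) * (pl$pixel_mm / 10)^2
  wf <- make_waveform(waveform_spec("sinusoid", amplitude = 7 * area_cm2))
  sim <- make_velocity_series(pl, wf)
  true_v <- wf$values / area_cm2             # cm/s at every ROI pixel
  got <- sim$series$v[16, 16, ]
  expected <- ifelse(true_v > 5, true_v - 10,
                     ifelse(true_v < -5, true_v + 10, true_v))
  # hand-checked pixels at the aliased peak phases
  expect_equal(got, expected, tolerance = 1e-10)
  expect_equal(got[9], 7 - 10, tolerance = 1e-10)   # quarter-cycle peak
  expect_true(all(abs(sim$series$v) <= 5 + 1e-12))
  expect_false(sim$series$alias_warning)
})

test_that("super-venc velocities without aliasing raise the warning flag", {
  pl <- plane_spec(grid_size = 32, pixel_mm = 1, venc = 5,
                   roi = list(type = "disc", center = c(16, 16),
                              radius_mm = 3), aliasing = FALSE)
  mask <- csfpulse:::.resolve_roi(pl)$union
  area_cm2 <- sum(mask) * (pl$pixel_mm / 10)^2
  wf <- make_waveform(waveform_spec("sinusoid", amplitude = 7 * area_cm2))
  expect_warning(sim <- make_velocity_series(pl, wf), "venc")
  expect_true(sim$series$alias_warning)
})

test_that("parabolic profile preserves total flow for disc ROIs", {
  pl <- plane_spec(grid_size = 64, venc = 10,
                   roi = list(type = "disc", center = c(32, 32),
                              radius_mm = 6),
                   velocity_profile = "parabolic")
  wf <- waveform_spec("sinusoid", amplitude = 2)
  sim <- make_velocity_series(pl, wf)
  fc <- compute_flow_curve(sim$series, sim$truth_mask)
  expect_equal(fc$values, sim$truth_curve$values, tolerance = 1e-10)
  # centre velocity roughly twice the spatial mean (plug-flow comparison)
  centre <- sim$series$v[32, 32, 9]
  mean_v <- mean(sim$series$v[, , 9][sim$truth_mask$mask])
  expect_equal(centre / mean_v, 2, tolerance = 0.15)
})

test_that("multi-vessel planes split the flow by the requested fractions", {
  pl <- plane_spec(grid_size = 64, venc = 60,
                   roi = list(type = "multi_vessel", vessels = list(
                     list(center = c(20, 20), radius_mm = 3,
                          flow_fraction = 0.7),
                     list(center = c(44, 44), radius_mm = 3,
                          flow_fraction = 0.3))))
  wf <- waveform_spec("arterial_like", amplitude = 2, mean_offset = 8)
  sim <- make_velocity_series(pl, wf)
  d <- csfpulse:::.pixel_dist_mm(pl$grid_size, pl$pixel_mm, c(20, 20))
  m1 <- d <= 3
  fc1 <- compute_flow_curve(sim$series, m1)
  expect_equal(mean_flow(fc1), 0.7 * 8, tolerance = 1e-9)
  fc_all <- compute_flow_curve(sim$series, sim$truth_mask)
  expect_equal(fc_all$values, sim$truth_curve$values, tolerance = 1e-9)
})

test_that("NIfTI round trip preserves velocities and metadata", {
  sim <- cervical_plane(sv_ul = 300, noise_sd = 0.1, seed = 5)
  path <- file.path(tempdir(), "cerv_test.nii.gz")
  write_velocity_series(sim$series, path)
  back <- read_velocity_series(path)
  expect_equal(back$v, unclass(sim$series$v), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$venc, 5)
  expect_equal(back$pixel_mm, 0.6)
  expect_equal(back$compartment, "csf_cervical")
  mpath <- file.path(tempdir(), "cerv_mask.nii.gz")
  write_roi_mask(sim$truth_mask, mpath)
  expect_equal(read_roi_mask(mpath), unclass(sim$truth_mask$mask),
               ignore_attr = TRUE)
  unlink(c(path, sub("\\.nii\\.gz$", ".json", path), mpath))
})

test_that("ROI geometry errors are caught", {
  expect_error(make_velocity_series(
    plane_spec(grid_size = 16,
               roi = list(type = "disc", center = c(8, 8),
                          radius_mm = 10)),
    waveform_spec("sinusoid")), "border")
  expect_error(plane_spec(pixel_mm = 0), "pixel_mm")
  expect_error(plane_spec(venc = -1), "venc")
})
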