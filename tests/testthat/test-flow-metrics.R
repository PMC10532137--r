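test_that("flow curve equals a per-pixel brute-force summation exactly", {
  sim <- cervical_plane(sv_ul = 450, noise_sd = 0.2, seed = 11)
  fc <- compute_flow_curve(sim$series, sim$truth_mask)
  # brute-force oracle: explicit loop over pixels and phases
  a_cm2 <- (sim$series$pixel_mm / 10)^2
  idx <- which(sim$truth_mask$mask, arr.ind = TRUE)
  brute <- numeric(32)
  for (k in 1:32) {
    s <- 0
    for (i in seq_len(nrow(idx)))
      s <- s + sim$series$v[idx[i, 1], idx[i, 2], k] * a_cm2
    brute[k] <- s
  }
  # agreement to rounding only: the loop accumulates in a different order
  expect_equal(fc$values, brute, tolerance = 1e-13)
})

test_that("uniform unit velocity over 100 pixels gives 0.36 mL/s", {
  v <- array(0, dim = c(20, 20, 32))
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  v[rep(m, 32)] <- 1                       # 1 cm/s in 100 pixels
  s <- velocity_series(v, pixel_mm = 0.6, venc = 5)
  fc <- compute_flow_curve(s, m)
  expect_equal(fc$values, rep(0.36, 32), tolerance = 1e-12)
  expect_equal(compute_flow_curve(
    velocity_series(array(0, dim(v)), pixel_mm = 0.6, venc = 5), m)$values,
    rep(0, 32))
  expect_error(compute_flow_curve(s, matrix(FALSE, 20, 20)), "empty")
})

test_that("arterial and venous sums convert to mL/min correctly", {
  const_curve <- function(val) flow_curve(rep(val, 32))
  art <- cerebral_arterial_flow(const_curve(4), const_curve(4),
                                const_curve(2))
  expect_equal(art$cbfa_ml_min, 600)
  expect_equal(art$curve$values, rep(10, 32))
  # additive identity
  art0 <- cerebral_arterial_flow(const_curve(4), const_curve(4),
                                 const_curve(0))
  expect_equal(art0$cbfa_ml_min, 480)

  ven <- cerebral_venous_flow(const_curve(3), const_curve(2))
  expect_equal(ven$cbfv_ml_min, 300)
  ven_swap <- cerebral_venous_flow(const_curve(2), const_curve(3))
  expect_equal(ven_swap$curve$values, ven$curve$values)

  expect_error(cerebral_arterial_flow(const_curve(1), const_curve(1),
                                      flow_curve(rep(1, 32), cycle_s = 2)),
               "cycle")
})

test_that("alpha factor and sinus participation follow their definitions", {
  expect_equal(alpha_factor(500, 500), 1)
  expect_equal(alpha_factor(728, 500), 1.456)
  expect_error(alpha_factor(500, 0), "positive")
  expect_warning(a <- alpha_factor(400, 500), "below 1")
  expect_equal(a, 0.8)

  expect_equal(sinus_participation(2), 50)
  expect_equal(sinus_participation(1), 100)
  expect_equal(sinus_participation(4), 25)
  expect_error(sinus_participation(0), "positive")
})

test_that("alpha correction equalises the venous and arterial means", {
  set.seed(21)
  for (i in 1:5) {
    art <- flow_curve(abs(rnorm(32, 10, 3)))
    ven <- flow_curve(abs(rnorm(32, 7, 2)))
    alpha <- alpha_factor(mean_flow(art, "ml_min"),
                          mean_flow(ven, "ml_min"))
    corr <- corrected_venous_curve(ven, alpha)
    expect_equal(mean_flow(corr), mean_flow(art), tolerance = 1e-12)
    av <- arteriovenous_curve(art, corr)
    expect_lt(abs(mean(av$values)) / max(abs(av$values)), 1e-9)
  }
  # alpha = 1 leaves the curve untouched; alpha = 2 doubles every sample
  ven <- flow_curve(abs(rnorm(32, 5, 1)))
  expect_equal(corrected_venous_curve(ven, 1)$values, ven$values)
  expect_equal(corrected_venous_curve(ven, 2)$values, 2 * ven$values)
})

test_that("arteriovenous curve of identical inputs vanishes", {
  x <- flow_curve(abs(rnorm(32, 8, 2)))
  expect_equal(arteriovenous_curve(x, x)$values, rep(0, 32))
})

test_that("an arterial phase lead yields a positive early-cycle lobe", {
  art <- make_waveform(waveform_spec("arterial_like", amplitude = 3,
                                     mean_offset = 10))
  ven <- make_waveform(waveform_spec("arterial_like", amplitude = 2,
                                     mean_offset = 10, phase_shift = 0.75))
  alpha <- alpha_factor(mean_flow(art, "ml_min"), mean_flow(ven, "ml_min"))
  av <- arteriovenous_curve(art, corrected_venous_curve(ven, alpha))
  early <- mean(av$values[3:10])
  expect_gt(early, 0)
})

test_that("vascular stroke volume scales linearly and matches A*T/pi", {
  av <- make_waveform(waveform_spec("sinusoid", amplitude = 2.6,
                                    period = 1))
  expect_equal(blood_stroke_volume(av), 2.6 / pi, tolerance = 5e-3)
  expect_equal(blood_stroke_volume(flow_curve(rep(0, 32))), 0)
  scaled <- flow_curve(3 * av$values, cycle_s = 1)
  expect_equal(blood_stroke_volume(scaled), 3 * blood_stroke_volume(av),
               tolerance = 1e-12)
})

test_that("noise-free planes give end-to-end recovery within 5%", {
  sim <- cervical_plane(sv_ul = 587)
  seg <- segment_pulsatile(sim$series, seed = c(32, 43))
  fc <- compute_flow_curve(sim$series, seg)
  expect_equal(stroke_volume(fc), sim$truth_sv_ul, tolerance = 0.05)
  expect_equal(mean_flow(fc, "ml_min"), sim$truth_mean_flow_ml_min,
               tolerance = 0.05)
  expect_equal(peak_amplitude(fc), peak_amplitude(sim$truth_curve),
               tolerance = 0.05)
})
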