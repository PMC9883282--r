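test_that("build_curve restricts to the ramp and orders by time", {
  fx <- fx_noisy_ramp()
  curve <- build_curve(fx$seg, window = c(7, 15))
  expect_equal(nrow(curve), sum(fx$seg$t_s >= 7 & fx$seg$t_s <= 15))
  expect_true(!is.unsorted(curve$t_s))
  expect_true(attr(curve, "has_collapse"))
  expect_error(build_curve(fx$seg, window = c(100, 101)), "empty")
  shallow <- build_curve(fx$seg, window = c(0, 1))
  expect_false(attr(shallow, "has_collapse"))
})

test_that("collapse force is the interpolated first crossing", {
  curve <- data.frame(t_s = 1:2, force_N = c(5, 6), area_mm2 = c(1.0, 0.4),
                      band_mm2 = 0)
  expect_equal(estimate_collapse_force(curve), 5 + 0.5 / 0.6)
  first_low <- data.frame(t_s = 1:3, force_N = c(4, 5, 6),
                          area_mm2 = c(0.3, 0.2, 0.1), band_mm2 = 0)
  expect_equal(estimate_collapse_force(first_low), 4)
  open_curve <- data.frame(t_s = 1:3, force_N = 1:3, area_mm2 = c(3, 2, 1),
                           band_mm2 = 0)
  expect_error(estimate_collapse_force(open_curve), "below")
})

test_that("collapse force tracks the phantom truth crossing", {
  for (fx in list(fx_clean_ramp(), fx_noisy_ramp())) {
    curve <- build_curve(fx$seg, window = c(7, 15))
    cf <- estimate_collapse_force(curve)
    expect_lt(abs(cf - truth_collapse_crossing(fx$acq)), 0.2)
  }
})

test_that("cardiac envelope crossings match closed-form line solutions", {
  # hand-built two-line dataset: minima on a = 4 - 0.5 F, maxima on
  # a = 5 - 0.5 F; crossings of 0.5 are F = 7 and F = 9
  f <- seq(1, 8.4, by = 0.2)
  a <- ifelse(seq_along(f) %% 2 == 0, 5 - 0.5 * f, 4 - 0.5 * f)
  curve <- data.frame(t_s = seq_along(f), force_N = f, area_mm2 = a,
                      band_mm2 = 0)
  env <- cardiac_envelope_uncertainty(curve)
  expect_false(env$degenerate)
  expect_equal(env$cardiac_low, 7, tolerance = 1e-6)
  expect_equal(env$cardiac_high, 9, tolerance = 1e-6)

  # no oscillation -> degenerate bounds equal to the collapse force
  fx <- fx_clean_ramp()
  curve0 <- build_curve(fx$seg, window = c(7, 15))
  env0 <- cardiac_envelope_uncertainty(curve0)
  expect_true(env0$degenerate)
  expect_equal(env0$cardiac_low, estimate_collapse_force(curve0))
  expect_equal(env0$cardiac_high, env0$cardiac_low)
})

test_that("segmentation force uncertainty divides band by local slope", {
  curve <- data.frame(t_s = 1:20, force_N = seq(1, 10.5, 0.5),
                      area_mm2 = pmax(5.5 - 0.5 * seq(1, 10.5, 0.5), 0.05),
                      band_mm2 = 0)
  expect_equal(segmentation_force_uncertainty(curve, band_mm2 = 0.25), 0.5,
               tolerance = 1e-6)
  expect_equal(segmentation_force_uncertainty(curve, band_mm2 = 0), 0)
  flat <- data.frame(t_s = 1:10, force_N = 1:10, area_mm2 = 2, band_mm2 = 0)
  expect_error(segmentation_force_uncertainty(flat, 0.25), "degenerate")

  # phantom: within 50% of the finite-difference truth-curve oracle
  fx <- fx_noisy_ramp()
  curve <- build_curve(fx$seg, window = c(7, 15))
  tc <- truth_curve(fx$acq)
  sub <- tc[tc$area_mm2 < 5 & tc$area_mm2 > 0.5, ]
  slope_true <- abs(coef(lm(area_mm2 ~ force_N, sub))[2])
  u <- segmentation_force_uncertainty(curve, band_mm2 = 0.25)
  expect_lt(abs(u - 0.25 / slope_true), 0.5 * (0.25 / slope_true))
})

test_that("collapse estimate combines components with valid invariants", {
  fx <- fx_noisy_ramp()
  est <- estimate_collapse(build_curve(fx$seg, window = c(7, 15)))
  expect_s3_class(est, "collapse_estimate")
  expect_lte(est$cardiac_low, est$collapse_force)
  expect_gte(est$cardiac_high, est$collapse_force)
  expect_gte(est$segmentation_uncertainty, 0)
  expect_equal(est$total_uncertainty,
               (est$cardiac_high - est$cardiac_low) / 2 +
                 est$segmentation_uncertainty)
  expect_gte(est$total_uncertainty, est$segmentation_uncertainty)
  expect_false(est$below_min_contact)
})

test_that("collapse force rises with baseline pressure, falls with c", {
  # property on truth-level curves (no imaging in the loop)
  cfs <- vapply(c(2, 5, 10, 15), function(b) {
    pp <- phantom_params(speckle_level = 0, cardiac_amplitude = 0,
                         baseline_pressure = b)
    t <- seq(0, 10, 0.05)
    f <- 2.5 * t
    a <- tube_law_area(b - pp$force_transfer_coeff * f, pp)
    estimate_collapse_force(data.frame(t_s = t, force_N = f, area_mm2 = a,
                                       band_mm2 = 0))
  }, numeric(1))
  expect_true(all(diff(cfs) > 0))

  cfs_c <- vapply(c(0.6, 0.9, 1.2), function(cc) {
    pp <- phantom_params(speckle_level = 0, cardiac_amplitude = 0,
                         force_transfer_coeff = cc)
    t <- seq(0, 10, 0.05)
    f <- 2.5 * t
    a <- tube_law_area(5 - cc * f, pp)
    estimate_collapse_force(data.frame(t_s = t, force_N = f, area_mm2 = a,
                                       band_mm2 = 0))
  }, numeric(1))
  expect_true(all(diff(cfs_c) < 0))
})
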