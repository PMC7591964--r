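test_that("deflection converts to force by Hooke's law", {
  # the reference cantilever: k = 0.01 N/m, 100 nm deflection -> 1 nN
  expect_equal(deflection_to_force(100e-9, 0.01), 1e-9)
  expect_equal(deflection_to_force(5e-9, 0.01, d0 = 5e-9), 0)
  d <- c(1e-9, 3e-9, 7e-9)
  expect_equal(deflection_to_force(3 * d, 0.01), 3 * deflection_to_force(d, 0.01))
  expect_equal(deflection_to_force(d, 0.02), 2 * deflection_to_force(d, 0.01))
  expect_error(deflection_to_force(d, -0.01), "spring constant")
})

test_that("contact point is recovered exactly on noise-free curves", {
  fc <- gen_hertzian_raw(E = 5160, noise = 0, seed = 1)
  expect_lte(abs(cp_step_error(fc)), 1)
  cp <- find_contact_point(fc)
  expect_equal(cp$z0, attr(fc, "metadata")$z0, tolerance = 1e-9)
  expect_gt(cp$quality, 0.99)
})

test_that("contact point stays within a few grid steps under 2% force noise", {
  errs <- vapply(1:50, function(s) {
    cp_step_error(gen_hertzian_raw(E = 5160, noise = 0.02, seed = s))
  }, numeric(1))
  expect_lte(median(abs(errs)), 5)
})

test_that("flat curves raise 'no contact detected' for both methods", {
  z <- seq(0, 1e-6, length.out = 200)
  flat <- force_curve(z, rep(0, 200), 0.01)
  expect_error(find_contact_point(flat), "no contact detected")
  withr::with_seed(3, {
    noisy_flat <- force_curve(z, rnorm(200, sd = 1e-9), 0.01)
  })
  expect_error(find_contact_point(noisy_flat), "no contact detected")
  expect_error(find_contact_point(noisy_flat, method = "threshold"), "no contact")
  expect_equal(analyze_curve(flat)$status, "no_contact")
})

test_that("threshold method locates contact on clean curves", {
  fc <- gen_hertzian_raw(E = 5160, noise = 0, seed = 1)
  expect_lte(abs(cp_step_error(fc, method = "threshold")), 40)
})

test_that("baseline tilt is detected and corrected", {
  fc <- gen_hertzian_raw(E = 5160, noise = 0.01, seed = 11)
  slope <- 5e-3 # 5 nm of spurious deflection per um of travel
  tilted <- force_curve(fc$z, fc$d + slope * fc$z, spring_constant(fc),
    metadata = attr(fc, "metadata")
  )
  cp <- find_contact_point(tilted)
  expect_equal(cp$tilt_slope, slope, tolerance = 0.15)
  fit <- fit_sneddon(to_indentation(tilted, cp), cone25)
  expect_equal(fit$E, 5160, tolerance = 0.05)
})

test_that("conversion to indentation applies h = (z - z0) - (d - d0) exactly", {
  fc <- gen_hertzian_raw(E = 5160, noise = 0, seed = 4)
  md <- attr(fc, "metadata")
  ic <- to_indentation(fc, true_contact_point(fc))
  a <- md$a
  # noise-free inversion reproduces the generating curve to machine precision
  expect_equal(ic$P, a * ic$h^2, tolerance = 1e-12)
  expect_equal(max(ic$h), md$h_max, tolerance = 1e-12)
})

test_that("soft-sample limit gives h ~ z - z0", {
  # negligible deflection: stiff cantilever, soft sample
  n <- 200
  z0 <- 1e-7
  z <- seq(0, 1e-6, length.out = n)
  d <- ifelse(z > z0, 1e-12 * (z - z0) / 1e-6, 0)
  fc <- force_curve(z, d, 1)
  cp <- structure(
    list(
      index = which(z > z0)[1], z0 = z0, d0 = 0, tilt_slope = 0,
      method = "truth", quality = 1
    ),
    class = "contact_point"
  )
  ic <- to_indentation(fc, cp)
  expect_equal(ic$h, z[z > z0] - z0, tolerance = 1e-5)
})

test_that("rigid contact (all deflection, no indentation) cannot form a depth curve", {
  n <- 100
  z <- seq(0, 1e-6, length.out = n)
  z0 <- z[50]
  d <- pmax(z - z0, 0)
  fc <- force_curve(z, d, 0.01)
  cp <- structure(
    list(index = 50L, z0 = z0, d0 = 0, tilt_slope = 0, method = "truth", quality = 1),
    class = "contact_point"
  )
  expect_error(to_indentation(fc, cp), "fewer than 4")
})

test_that("processed depth is non-negative and strictly increasing for all generator modes", {
  cases <- list(
    gen_hertzian_raw(5160, noise = 0.02, seed = 21),
    gen_hertzian_raw(5160, noise = 0.05, seed = 22),
    gen_depth_dependent_raw(5e3, mode = "bilayer", E_deep = 5e4, noise = 0.01, seed = 23),
    gen_depth_dependent_raw(5e3,
      mode = "quartic",
      a2 = 2 * sneddon_prefactor(5e3, cone25) / 1e-12, noise = 0.02, seed = 24
    )
  )
  for (fc in cases) {
    ic <- to_indentation(fc, true_contact_point(fc))
    expect_true(all(ic$h >= 0))
    expect_true(all(diff(ic$h) > 0))
  }
})

test_that("depth truncation keeps the shallow segment intact", {
  ic <- make_power_curve(2042, 2, 1000e-9, 500)
  tr <- truncate_depth(ic, 200e-9)
  expect_lte(max(tr$h), 200e-9)
  expect_equal(tr$P, 2042 * tr$h^2)
  # identity when the limit exceeds the curve
  expect_equal(truncate_depth(ic, 2e-6)$h, ic$h)
  expect_error(truncate_depth(ic, 1e-9), "fewer than 4")
  expect_error(truncate_depth(ic, -1), "h_limit")
})

test_that("full pipeline recovers the modulus within 2% at 2% force noise", {
  rel_err <- vapply(1:20, function(s) {
    fc <- gen_hertzian_raw(E = 5160, noise = 0.02, seed = 400 + s)
    fit <- fit_sneddon(to_indentation(fc), cone25)
    fit$E / 5160 - 1
  }, numeric(1))
  expect_lte(median(abs(rel_err)), 0.02)
})
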