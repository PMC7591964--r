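test_that("W = f(h^3) is perfectly linear for a Hertzian conical curve", {
  wp <- work_numeric(make_power_curve(2042, 2, 1149e-9, 1000))
  lt <- linearity_test(wp)
  expect_gt(lt$r_squared, 0.999999)
  expect_true(lt$is_linear)
  # slope = (W/V) * (8 tan^2(theta) / (3 pi^2)) when the cone volume form holds
  vol_coef <- 8 * tan(25 * pi / 180)^2 / (3 * pi^2)
  expect_equal(lt$slope, wv_conical_from_E(5158.9858, cone25) * vol_coef,
    tolerance = 1e-3
  )
})

test_that("the published depth-dependent work curve fails the linearity test", {
  # work data reconstructed from the printed polynomial coefficients
  c2 <- 5e21
  c1 <- 2014
  c0 <- 3.548e-18
  h <- seq(1e-9, 487e-9, length.out = 1000)
  x <- h^3
  wp <- work_numeric(indentation_curve(h, rep(1e-9, 1000)))
  wp$W <- c2 * x^2 + c1 * x + c0
  lt <- linearity_test(wp)
  expect_false(lt$is_linear)
  # independent check of the R^2 value against a direct regression
  expect_equal(lt$r_squared, summary(stats::lm(wp$W ~ x))$r.squared)
  expect_equal(lt$r_squared, 0.99656, tolerance = 1e-4)
})

test_that("linearity test rejects degenerate profiles", {
  h <- seq(1e-9, 1e-6, length.out = 20)
  wp <- work_numeric(indentation_curve(h, rep(0, 20)))
  expect_error(linearity_test(wp), "degenerate")
})

test_that("polynomial fit recovers the printed coefficients from self-generated data", {
  c2 <- 5e21
  c1 <- 2014
  c0 <- 3.548e-18
  h <- seq(1e-9, 487e-9, length.out = 500)
  x <- h^3
  wp <- work_numeric(indentation_curve(h, rep(1e-9, 500)))
  wp$W <- c2 * x^2 + c1 * x + c0
  poly <- fit_wv_polynomial(wp)
  expect_equal(poly$c2, c2, tolerance = 1e-3)
  expect_equal(poly$c1, c1, tolerance = 1e-3)
  expect_equal(poly$c0, c0, tolerance = 1e-3)
  expect_gt(poly$r_squared, 0.999999)
  td <- tidy(poly)
  expect_equal(td$estimate[td$term == "c1_J_per_m3"], poly$c1)
})

test_that("purely linear work collapses to c2 ~ 0 and degenerate work errors", {
  wp <- work_numeric(make_power_curve(2042, 2, 1149e-9, 500))
  poly <- fit_wv_polynomial(wp)
  # quadratic contribution negligible against the linear term at full depth
  x_max <- max(wp$h)^3
  expect_lt(abs(poly$c2) * x_max^2, 1e-4 * poly$c1 * x_max)
  h <- seq(1e-9, 1e-6, length.out = 20)
  wp0 <- work_numeric(indentation_curve(h, rep(0, 20)))
  expect_error(fit_wv_polynomial(wp0), "degenerate")
})

test_that("W/V at depth reproduces the published 380/487 nm evaluations", {
  c2 <- 5e21
  c1 <- 2014
  c0 <- 3.548e-18
  h <- seq(1e-9, 487e-9, length.out = 500)
  x <- h^3
  wp <- work_numeric(indentation_curve(h, rep(1e-9, 500)))
  wp$W <- c2 * x^2 + c1 * x + c0
  poly <- fit_wv_polynomial(wp)
  # frozen oracle values from direct evaluation of the printed coefficients
  expect_equal(wv_at_depth(poly, 380e-9, cone25) / 1e3, 40.0508, tolerance = 1e-3)
  expect_equal(wv_at_depth(poly, 430e-9, cone25) / 1e3, 41.8064, tolerance = 1e-3)
  expect_equal(wv_at_depth(poly, 487e-9, cone25) / 1e3, 44.6330, tolerance = 1e-3)
  expect_warning(wv_at_depth(poly, 600e-9, cone25), "extrapolating")
})

test_that("with c2 = c0 = 0 the polynomial W/V is the constant of the linear case", {
  poly <- structure(
    list(c2 = 0, c1 = 2014, c0 = 0, r_squared = 1, domain = c(0, 1e-6), n = 100),
    class = "wv_poly"
  )
  vol_coef <- 8 * tan(25 * pi / 180)^2 / (3 * pi^2)
  for (h in c(50e-9, 380e-9, 1e-6)) {
    expect_equal(wv_at_depth(poly, h, cone25), 2014 / vol_coef, tolerance = 1e-14)
  }
})

test_that("W/V profile is flat for Hertzian curves and increasing for stiffening ones", {
  a <- sneddon_prefactor(5190, cone25)
  wvp <- wv_profile(work_numeric(make_power_curve(a, 2, 1e-6, 2000)), cone25)
  expect_equal(mean(wvp$wv) / 1e3, 11.655, tolerance = 1e-3)
  expect_lt(sd(wvp$wv) / mean(wvp$wv), 1e-4)
  # stiffening quartic load: strictly increasing ratio profile
  h <- seq(0, 1e-6, length.out = 1000)
  ic <- indentation_curve(h, a * h^2 + (2 * a / 1e-12) * h^4)
  wvp2 <- wv_profile(work_numeric(ic), cone25)
  expect_true(all(diff(wvp2$wv) > 0))
  # zero work gives zero ratios
  h4 <- seq(0, 1e-6, length.out = 50)
  wvp0 <- wv_profile(work_numeric(indentation_curve(h4, rep(0, 50))), cone25)
  expect_true(all(wvp0$wv == 0))
})

test_that("linear-range detection returns full depth for Hertzian profiles", {
  wp <- work_numeric(make_power_curve(2042, 2, 1e-6, 500))
  expect_equal(linear_range_detect(wp), 1e-6)
})

test_that("linear-range detection localises a bilayer onset at 400 nm", {
  fc <- gen_depth_dependent_raw(5e3,
    mode = "bilayer", E_deep = 5e4,
    onset = 400e-9, noise = 0, seed = 2
  )
  wp <- work_numeric(to_indentation(fc))
  h_lim <- linear_range_detect(wp)
  expect_gte(h_lim, 300e-9)
  expect_lte(h_lim, 500e-9)
})

test_that("strong nonlinearity from the origin yields no linear range", {
  h <- seq(1e-9, 1e-6, length.out = 500)
  x <- h^3
  wp <- work_numeric(indentation_curve(h, rep(1e-9, 500)))
  wp$W <- (x / max(x))^2 * 1e-15
  expect_error(linear_range_detect(wp), "no linear range")
})

test_that("linear-range depth never grows when the threshold tightens", {
  fc <- gen_depth_dependent_raw(5e3,
    mode = "bilayer", E_deep = 5e4, noise = 0, seed = 5
  )
  wp <- work_numeric(to_indentation(fc))
  lims <- vapply(
    c(0.99, 0.999, 0.9999),
    function(th) tryCatch(linear_range_detect(wp, threshold = th), error = function(e) 0),
    numeric(1)
  )
  expect_true(all(diff(lims) <= 0))
})

test_that("modulus from mean W/V agrees with the Sneddon fit on linear curves", {
  fc <- gen_hertzian_raw(E = 5160, noise = 0, seed = 9)
  ic <- to_indentation(fc)
  fit <- fit_sneddon(ic, cone25)
  wvp <- wv_profile(work_numeric(ic), cone25)
  E_wv <- E_from_wv(mean(wvp$wv), cone25)
  expect_lt(abs(E_wv - fit$E) / fit$E, 0.01)
})

test_that("indentation beyond 10% of a declared thickness triggers a substrate warning", {
  fc <- gen_hertzian_raw(E = 5160, noise = 0, seed = 10)
  cfg <- analysis_config(thickness = 2e-6)
  expect_warning(analyze_curve(fc, cfg), "thickness")
  cfg_thick <- analysis_config(thickness = 50e-6)
  expect_silent(analyze_curve(fc, cfg_thick))
})
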