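test_that("closed-form work matches a/(m+1) h^(m+1) and the worked example", {
  # the published fit P = 2042 h^2 to 1149 nm: W = a h^3 / 3
  expect_equal(work_closed_form(2042, 2, 1149e-9), 1.03251072e-15,
    tolerance = 1e-8
  )
  expect_equal(work_closed_form(2042, 2, 0), 0)
  expect_equal(work_closed_form(3, 2, 1), 1)
})

test_that("trapezoid work converges to the closed form at O(n^-2)", {
  errs <- vapply(c(250L, 500L, 1000L), function(n) {
    wp <- work_numeric(make_power_curve(2042, 2, 1149e-9, n))
    abs(wp$W[n] - work_closed_form(2042, 2, 1149e-9)) /
      work_closed_form(2042, 2, 1149e-9)
  }, numeric(1))
  expect_lt(errs[3], 1e-4)
  # second-order convergence: halving the step divides the error by ~4
  expect_equal(errs[1] / errs[2], 4, tolerance = 0.1)
  expect_equal(errs[2] / errs[3], 4, tolerance = 0.1)
})

test_that("trapezoid work is exact for linear loads and zero for zero loads", {
  h <- seq(0, 1e-6, length.out = 5)
  cl <- 2e-3 # N/m
  wp <- work_numeric(indentation_curve(h, cl * h))
  expect_equal(wp$W, cl * h^2 / 2)
  wp0 <- work_numeric(indentation_curve(h, rep(0, 5)))
  expect_equal(wp0$W, rep(0, 5))
})

test_that("work profile rejects non-monotonic depth naming the first offender", {
  expect_error(
    indentation_curve(c(0, 1e-9, 0.5e-9, 2e-9, 3e-9), rep(1e-9, 5)),
    "index 3"
  )
})

test_that("general W/V reduces exactly to the conical and spherical forms", {
  E <- 5190
  nu <- 0.5
  a <- sneddon_prefactor(E, cone25, nu)
  cc <- contact_radius_coefficient(a, 2, E, nu, pi / 2)
  for (h in c(100e-9, 500e-9, 1000e-9)) {
    expect_equal(
      wv_general(a, 2, pi / 2, cc, h), wv_conical_from_E(E, cone25, nu),
      tolerance = 1e-14
    )
  }
  # depth-independence at m = 2 is exact, not approximate
  expect_identical(
    wv_general(a, 2, pi / 2, cc, 100e-9), wv_general(a, 2, pi / 2, cc, 1000e-9)
  )
  R <- 1
  sph <- indenter_sphere(R)
  asph <- hertz_sphere_prefactor(1, sph, nu = 0)
  csph <- contact_radius_coefficient(asph, 3 / 2, 1, 0, 2)
  expect_equal(wv_general(asph, 3 / 2, 2, csph, 1), 32 / (15 * pi),
    tolerance = 1e-14
  )
  expect_equal(
    wv_general(asph, 3 / 2, 2, csph, 0.25), wv_spherical(1, sph, 0.25, nu = 0),
    tolerance = 1e-14
  )
})

test_that("conical W/V from E reproduces the 11.65 kJ/m^3 worked value", {
  wv <- wv_conical_from_E(5190, cone25, nu = 0.5)
  expect_equal(wv, 11655.2992, tolerance = 1e-6)
  expect_equal(wv / 1e3, 11.65, tolerance = 5e-4)
  expect_equal(wv_conical_from_E(1, indenter_cone(45), nu = 0), pi / 4)
  expect_equal(wv_conical_from_E(0, cone25), 0)
})

test_that("E_from_wv inverts the conical relation and the worked 5.19 kPa value", {
  expect_equal(E_from_wv(11.65e3, cone25, nu = 0.5), 5187.6403, tolerance = 1e-6)
  expect_equal(round(E_from_wv(11.65e3, cone25, nu = 0.5) / 1e3, 2), 5.19)
  expect_equal(E_from_wv(pi / 4, indenter_cone(45), nu = 0), 1)
  for (E in c(120, 5.19e3, 4.2e4)) {
    expect_equal(E_from_wv(wv_conical_from_E(E, cone25), cone25), E,
      tolerance = 1e-14
    )
  }
  expect_error(E_from_wv(0, cone25), "W/V")
})

test_that("spherical W/V follows sqrt(h/R) scaling with the pi convention flagged", {
  sph <- indenter_sphere(1)
  expect_equal(wv_spherical(1, sph, 1, nu = 0), 32 / (15 * pi), tolerance = 1e-14)
  expect_equal(wv_spherical(1, sph, 0), 0)
  expect_equal(
    wv_spherical(1, sph, 4e-7, nu = 0), 2 * wv_spherical(1, sph, 1e-7, nu = 0)
  )
  expect_equal(
    wv_spherical(1, sph, 1, nu = 0, printed_form = TRUE),
    pi * wv_spherical(1, sph, 1, nu = 0)
  )
})

test_that("W/V in J/m^3 equals the same ratio computed through nJ/nm^3", {
  W <- work_closed_form(2042, 2, 1149e-9) # J
  V <- contact_volume(cone25, 1149e-9) # m^3
  expect_identical((W * 1e9) / (V * 1e27) * 1e18, W / V)
})

test_that("Sneddon fit recovers the printed prefactor and modulus exactly when noise-free", {
  fit <- fit_sneddon(make_power_curve(2042, 2, 1149e-9, 1000), cone25, nu = 0.5)
  expect_equal(fit$a, 2042, tolerance = 1e-12)
  expect_equal(fit$E, 5158.9858, tolerance = 1e-6)
  expect_equal(round(fit$E / 1e3, 2), 5.16)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("Sneddon fit round-trips a generated modulus and tolerates 5% force noise", {
  a10 <- sneddon_prefactor(1e4, cone25)
  fit <- fit_sneddon(make_power_curve(a10, 2, 1e-6, 500), cone25)
  expect_equal(fit$E, 1e4, tolerance = 1e-3)
  # Monte-Carlo: zero-mean force noise, SD = 5% of P(h_max), 1000 points
  E_hat <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      h <- seq(0, 1e-6, length.out = 1000)
      P <- a10 * h^2 + rnorm(1000, sd = 0.05 * a10 * 1e-12)
      fit_sneddon(indentation_curve(h, P), cone25)$E
    })
  }, numeric(1))
  expect_equal(mean(E_hat), 1e4, tolerance = 0.02)
})

test_that("Sneddon fit rejects degenerate input", {
  h <- seq(0, 1e-6, length.out = 20)
  expect_error(fit_sneddon(indentation_curve(h, rep(0, 20)), cone25), "degenerate")
  expect_error(
    fit_sneddon(indentation_curve(h[1:5], 2042 * h[1:5]^2), cone25),
    "at least 10"
  )
})

test_that("tidy and glance summarise a Sneddon fit", {
  fit <- fit_sneddon(make_power_curve(2042, 2, 1149e-9, 100), cone25)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$estimate[td$term == "a_N_per_m2"], 2042, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$nobs, 100)
  expect_equal(gl$r.squared, 1, tolerance = 1e-12)
})
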