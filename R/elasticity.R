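#' Test linearity of work against depth cubed
#'
#' For a conical indenter on a linear elastic half-space the contact volume
#' grows as h^3, so a constant W/V ratio is equivalent to the graph of
#' W = f(h^3) being a straight line. This test runs ordinary least squares of
#' the cumulative work against h^3 and classifies the curve as Hertzian when
#' the coefficient of determination reaches `threshold`.
#'
#' The default threshold 0.999 separates typical Hertzian curves (R^2 near
#' 0.9998) from clearly depth-dependent ones (R^2 near 0.96) with margin on
#' both sides; it is configurable.
#'
#' @param wp A `work_profile` from [work_numeric()], at least 10 points.
#' @param threshold R^2 required to call the curve linear, default 0.999.
#' @return An object of class `linearity_result`: list with `slope` (J/m^3
#'   scale), `intercept` (J), `r_squared`, `is_linear`, `threshold_used`,
#'   `n`.
#' @export
linearity_test <- function(wp, threshold = 0.999) {
  stopifnot(inherits(wp, "work_profile"))
  if (nrow(wp) < 10L) stop("linearity test needs at least 10 points", call. = FALSE)
  stopifnot(threshold > 0, threshold <= 1)
  x <- wp$h^3
  y <- wp$W
  if (stats::var(y) == 0) {
    stop("degenerate work profile: W is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      is_linear = r2 >= threshold,
      threshold_used = threshold,
      n = nrow(wp)
    ),
    class = "linearity_result"
  )
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf(
    "<W = f(h^3) linearity: R^2 = %.5f %s threshold %.4f -> %s>\n",
    x$r_squared, if (x$is_linear) ">=" else "<", x$threshold_used,
    if (x$is_linear) "linear (Hertzian)" else "depth-dependent"
  ))
  invisible(x)
}

#' @rdname tidy.wv_poly
#' @method glance linearity_result
#' @export
glance.linearity_result <- function(x, ...) {
  tibble::tibble(
    slope_J_per_m3 = x$slope, intercept_J = x$intercept,
    r.squared = x$r_squared, is_linear = x$is_linear,
    threshold = x$threshold_used, nobs = x$n
  )
}

#' Fit the depth-dependent work polynomial
#'
#' When W = f(h^3) is not linear the work profile is summarised by a
#' second-degree polynomial in x = h^3:
#' W = c2 x^2 + c1 x + c0. The quadratic term captures the leading
#' depth-dependence of the W/V ratio; the degree is fixed at 2 (higher
#' degrees are out of scope).
#'
#' @param wp A `work_profile`, at least 10 points.
#' @return An object of class `wv_poly`: list with `c2` (J/m^6), `c1`
#'   (J/m^3), `c0` (J), `r_squared`, `domain` (m, `c(0, h_max)`) and `n`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_wv_polynomial <- function(wp) {
  stopifnot(inherits(wp, "work_profile"))
  if (nrow(wp) < 10L) stop("polynomial fit needs at least 10 points", call. = FALSE)
  x <- wp$h^3
  y <- wp$W
  if (all(y == 0) || stats::var(y) == 0) {
    stop("degenerate work profile: cannot fit polynomial", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("rank-deficient design: cannot fit polynomial", call. = FALSE)
  structure(
    list(
      c2 = unname(cf[3]), c1 = unname(cf[2]), c0 = unname(cf[1]),
      r_squared = 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2),
      domain = c(0, max(wp$h)), n = nrow(wp)
    ),
    class = "wv_poly"
  )
}

#' @export
print.wv_poly <- function(x, ...) {
  cat(sprintf(
    "<W(h^3) polynomial: c2 = %.4g J/m^6, c1 = %.4g J/m^3, c0 = %.4g J, R^2 = %.5f>\n",
    x$c2, x$c1, x$c0, x$r_squared
  ))
  invisible(x)
}

#' Tidy depth-dependence fits
#'
#' @param x A `wv_poly` or `linearity_result`.
#' @param ... Unused.
#' @return A tibble of coefficients (`tidy`) or a one-row summary
#'   (`glance`).
#' @method tidy wv_poly
#' @export
tidy.wv_poly <- function(x, ...) {
  tibble::tibble(
    term = c("c2_J_per_m6", "c1_J_per_m3", "c0_J"),
    estimate = c(x$c2, x$c1, x$c0)
  )
}

#' @rdname tidy.wv_poly
#' @method glance wv_poly
#' @export
glance.wv_poly <- function(x, ...) {
  tibble::tibble(
    c2_J_per_m6 = x$c2, c1_J_per_m3 = x$c1, c0_J = x$c0,
    r.squared = x$r_squared, nobs = x$n, h_max_m = x$domain[2]
  )
}

#' W/V at a chosen depth from the fitted polynomial
#'
#' Evaluates the fitted work polynomial at depth h and divides by the conical
#' contact volume V = (8 tan^2(theta) / (3 pi^2)) h^3:
#' W/V = (c2 h^6 + c1 h^3 + c0) / V. With c2 = c0 = 0 this collapses to the
#' depth-independent constant c1 * 3 pi^2 / (8 tan^2 theta) of the linear
#' (Hertzian) case.
#'
#' @param poly A `wv_poly` from [fit_wv_polynomial()].
#' @param h Depth(s) in metres, > 0 (vectorised). Depths outside the fitted
#'   domain trigger an extrapolation warning, not an error.
#' @param indenter An [indenter_cone()].
#' @return W/V in J/m^3.
#' @export
wv_at_depth <- function(poly, h, indenter) {
  stopifnot(inherits(poly, "wv_poly"))
  assert_indenter(indenter)
  if (!is_cone(indenter)) stop("wv_at_depth() requires a cone", call. = FALSE)
  if (any(h <= 0)) stop("depth must be > 0", call. = FALSE)
  if (any(h > poly$domain[2])) {
    warning("depth outside the fitted domain: extrapolating", call. = FALSE)
  }
  x <- h^3
  W <- poly$c2 * x^2 + poly$c1 * x + poly$c0
  W / contact_volume(indenter, h)
}

#' Depth-resolved W/V profile
#'
#' Pointwise ratio of the cumulative work to the contact volume at each
#' depth, W(h) / V(h). For a noise-free Hertzian conical curve the profile is
#' constant; any trend flags depth-dependent mechanics. Ratios are reported
#' only for h >= `floor_frac` of the maximum depth because V vanishes as h^3
#' and the ratio amplifies noise near the contact point.
#'
#' @param wp A `work_profile` from [work_numeric()].
#' @param indenter An [indenter_cone()] or [indenter_sphere()].
#' @param floor_frac Smallest depth fraction reported, default 0.05.
#' @return A tibble of class `wv_profile` with columns `h` (m), `W` (J),
#'   `V` (m^3) and `wv` (J/m^3).
#' @export
wv_profile <- function(wp, indenter, floor_frac = 0.05) {
  stopifnot(inherits(wp, "work_profile"))
  assert_indenter(indenter)
  stopifnot(floor_frac >= 0, floor_frac < 1)
  keep <- wp$h >= floor_frac * max(wp$h) & wp$h > 0
  h <- wp$h[keep]
  W <- wp$W[keep]
  V <- contact_volume(indenter, h)
  out <- tibble::tibble(h = h, W = W, V = V, wv = W / V)
  class(out) <- c("wv_profile", class(out))
  out
}

#' Detect the linear (Hertzian) depth range
#'
#' Beyond some depth the W = f(h^3) graph of a thin or heterogeneous sample
#' departs from a straight line (substrate effect); only the initial linear
#' range should then be used for Hertzian analysis. This scans sub-profiles
#' `[0, h]`, expanding one sample at a time from a minimum of `min_frac` of
#' the depth range, and returns the largest depth whose sub-profile still
#' passes [linearity_test()] at `threshold`.
#'
#' @param wp A `work_profile`, at least 20 points.
#' @param threshold Linearity R^2 threshold, default 0.999.
#' @param min_frac Smallest depth fraction considered, default 0.2.
#' @return The depth limit `h_limit` in metres; `max(wp$h)` when the whole
#'   profile is linear. Errors with "no linear range" when even the shortest
#'   admissible sub-profile fails.
#' @export
linear_range_detect <- function(wp, threshold = 0.999, min_frac = 0.2) {
  stopifnot(inherits(wp, "work_profile"))
  if (nrow(wp) < 20L) {
    stop("linear-range detection needs at least 20 points", call. = FALSE)
  }
  x <- wp$h^3
  y <- wp$W
  n <- length(x)
  # prefix R^2 of y ~ x via cumulative sums (simple regression identity)
  cx <- cumsum(x)
  cy <- cumsum(y)
  cxx <- cumsum(x^2)
  cyy <- cumsum(y^2)
  cxy <- cumsum(x * y)
  k <- seq_len(n)
  sxx <- cxx - cx^2 / k
  syy <- cyy - cy^2 / k
  sxy <- cxy - cx * cy / k
  r2 <- ifelse(sxx > 0 & syy > 0, sxy^2 / (sxx * syy), NA_real_)
  first_k <- max(10L, which(wp$h >= min_frac * max(wp$h))[1])
  scan <- seq(first_k, n)
  pass <- !is.na(r2[scan]) & r2[scan] >= threshold
  if (!pass[1]) stop("no linear range", call. = FALSE)
  # stop at the first failure: once the substrate (or heterogeneity) bends
  # the W = f(h^3) graph, deeper prefixes can look spuriously straight again
  # because the stiff regime dominates the regression, so the largest
  # passing prefix is not a safe answer
  fail <- which(!pass)
  if (length(fail) == 0L) max(wp$h) else wp$h[scan[fail[1] - 1L]]
}

# Buckle's rule-of-thumb: indentation beyond 5-10% of the sample thickness
# risks substrate artifacts. Warning only; no enforcement procedure exists.
check_buckle <- function(h_max, thickness, frac = 0.10) {
  if (!is.null(thickness) && is.finite(thickness) && h_max > frac * thickness) {
    warning(sprintf(
      "indentation depth %.0f nm exceeds %.0f%% of the sample thickness (%.0f nm): substrate artifacts likely",
      h_max * 1e9, frac * 100, thickness * 1e9
    ), call. = FALSE)
  }
  invisible(NULL)
}
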