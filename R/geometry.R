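#' Indenter geometries
#'
#' Constructors for the two axisymmetric indenter geometries supported by the
#' package: a perfect cone of half-angle theta and a sphere of radius R.
#' Pyramidal AFM tips are handled through the cone with an effective
#' half-angle supplied by the user; no separate pyramid formula exists here.
#'
#' Angles are accepted in degrees at this boundary (the convention of AFM
#' probe datasheets) and stored in radians internally. All other lengths are
#' SI metres.
#'
#' @param half_angle Cone half-angle. Interpreted in degrees when
#'   `degrees = TRUE` (default), otherwise radians. Must lie strictly
#'   between 0 and 90 degrees.
#' @param degrees Is `half_angle` given in degrees?
#' @param radius Sphere radius in metres, > 0.
#' @return An object of class `afmwv_indenter`: a list with `shape`
#'   (`"cone"` or `"sphere"`) and either `half_angle` (radians) or
#'   `radius` (m).
#' @examples
#' indenter_cone(25)
#' indenter_sphere(5e-6)
#' @export
indenter_cone <- function(half_angle, degrees = TRUE) {
  stopifnot(is.numeric(half_angle), length(half_angle) == 1L, is.finite(half_angle))
  theta <- if (degrees) half_angle * pi / 180 else half_angle
  if (theta <= 0 || theta >= pi / 2) {
    stop("cone half-angle must lie strictly between 0 and 90 degrees", call. = FALSE)
  }
  structure(list(shape = "cone", half_angle = theta), class = "afmwv_indenter")
}

#' @rdname indenter_cone
#' @export
indenter_sphere <- function(radius) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("sphere radius must be > 0", call. = FALSE)
  structure(list(shape = "sphere", radius = radius), class = "afmwv_indenter")
}

#' @export
print.afmwv_indenter <- function(x, ...) {
  if (x$shape == "cone") {
    cat(sprintf("<indenter: cone, half-angle %.3f deg>\n", x$half_angle * 180 / pi))
  } else {
    cat(sprintf("<indenter: sphere, radius %.3g m>\n", x$radius))
  }
  invisible(x)
}

is_cone <- function(indenter) {
  inherits(indenter, "afmwv_indenter") && indenter$shape == "cone"
}
is_sphere <- function(indenter) {
  inherits(indenter, "afmwv_indenter") && indenter$shape == "sphere"
}
assert_indenter <- function(indenter) {
  if (!inherits(indenter, "afmwv_indenter")) {
    stop("`indenter` must be created with indenter_cone() or indenter_sphere()",
      call. = FALSE
    )
  }
  invisible(indenter)
}
assert_elastic <- function(E, nu) {
  stopifnot(is.numeric(E), is.numeric(nu))
  if (any(E < 0)) stop("Young's modulus must be non-negative", call. = FALSE)
  if (any(nu < 0 | nu > 0.5)) {
    stop("Poisson's ratio must lie in [0, 0.5]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Power-law contact prefactors
#'
#' For an axisymmetric indenter on a linear elastic half-space the
#' load-indentation relation is a power law, P = a h^m. `sneddon_prefactor()`
#' returns the conical prefactor of Sneddon's solution,
#' a = (2/pi) E tan(theta) / (1 - nu^2) with m = 2; `hertz_sphere_prefactor()`
#' returns the Hertzian spherical prefactor a = (4/3) E sqrt(R) / (1 - nu^2)
#' with m = 3/2.
#'
#' @param E Young's modulus in Pa (vectorised).
#' @param indenter An [indenter_cone()] (for `sneddon_prefactor`) or
#'   [indenter_sphere()] (for `hertz_sphere_prefactor`).
#' @param nu Poisson's ratio in `[0, 0.5]`; defaults to 0.5, the
#'   incompressible limit conventionally assumed for cells.
#' @return The prefactor `a` in N/m^2 (cone) or N/m^(3/2) (sphere).
#' @examples
#' # a fibroblast-like sample probed with a 25-degree conical tip
#' sneddon_prefactor(5160, indenter_cone(25)) # ~2042 N/m^2
#' @export
sneddon_prefactor <- function(E, indenter, nu = 0.5) {
  assert_indenter(indenter)
  if (!is_cone(indenter)) stop("sneddon_prefactor() requires a cone", call. = FALSE)
  assert_elastic(E, nu)
  (2 / pi) * E * tan(indenter$half_angle) / (1 - nu^2)
}

#' @rdname sneddon_prefactor
#' @export
hertz_sphere_prefactor <- function(E, indenter, nu = 0.5) {
  assert_indenter(indenter)
  if (!is_sphere(indenter)) {
    stop("hertz_sphere_prefactor() requires a sphere", call. = FALSE)
  }
  assert_elastic(E, nu)
  (4 / 3) * E * sqrt(indenter$radius) / (1 - nu^2)
}

#' Depth ratio b = h_max / h_c
#'
#' Ratio of the maximum indentation depth to the contact depth for an
#' indenter geometry: pi/2 for a cone (so h_c = (2/pi) h_max) and 2 for a
#' sphere.
#'
#' @inheritParams sneddon_prefactor
#' @return The dimensionless ratio `b`.
#' @export
geometric_b <- function(indenter) {
  assert_indenter(indenter)
  if (is_cone(indenter)) pi / 2 else 2
}

power_law_exponent <- function(indenter) {
  if (is_cone(indenter)) 2 else 3 / 2
}

#' Contact stiffness of a power-law contact
#'
#' S = dP/dh evaluated at the maximum depth: S = a m h_max^(m-1).
#'
#' @param a Power-law prefactor, N m^-m.
#' @param m Power-law exponent (> 1); 2 for a cone, 3/2 for a sphere.
#' @param h_max Maximum indentation depth in metres (> 0, vectorised).
#' @return Contact stiffness in N/m.
#' @export
contact_stiffness <- function(a, m, h_max) {
  stopifnot(a > 0, m > 1)
  if (any(h_max <= 0)) stop("h_max must be > 0", call. = FALSE)
  a * m * h_max^(m - 1)
}

#' Contact-radius coefficient
#'
#' The coefficient c in r_c = c h_c^(m-1), obtained by combining the contact
#' stiffness with the universal axisymmetric relation S / r_c = 2 E / (1 -
#' nu^2): c = a m (1 - nu^2) b^(m-1) / (2 E). For a cone with Sneddon's
#' prefactor this reduces exactly to tan(theta); for a sphere with the
#' Hertzian prefactor it reduces to sqrt(2 R).
#'
#' @inheritParams contact_stiffness
#' @param E Young's modulus in Pa.
#' @param nu Poisson's ratio.
#' @param b Depth ratio h_max / h_c, from [geometric_b()].
#' @return The coefficient c (units m^(2-m)).
#' @export
contact_radius_coefficient <- function(a, m, E, nu, b) {
  stopifnot(a > 0, m > 1, b > 0)
  if (E <= 0) stop("Young's modulus must be > 0", call. = FALSE)
  assert_elastic(E, nu)
  a * m * (1 - nu^2) * b^(m - 1) / (2 * E)
}

#' Contact volume of the immersed indenter part
#'
#' Volume of the portion of the indenter in contact with the sample,
#' V = integral of pi r(h)^2 dh from 0 to the contact depth h_c. For a cone
#' this evaluates to V = (8 tan^2(theta) / (3 pi^2)) h_max^3; for a sphere
#' (parabolic approximation r^2 = 2 R h, h_c = h_max / 2) to
#' V = pi R h_c^2.
#'
#' @inheritParams sneddon_prefactor
#' @param h_max Maximum indentation depth in metres (>= 0, vectorised).
#' @return Contact volume in m^3; 0 at `h_max = 0`.
#' @examples
#' contact_volume(indenter_cone(25), 1149e-9) # ~8.9e-20 m^3 = 8.9e7 nm^3
#' @export
contact_volume <- function(indenter, h_max) {
  assert_indenter(indenter)
  if (any(h_max < 0)) stop("h_max must be non-negative", call. = FALSE)
  if (is_cone(indenter)) {
    (8 * tan(indenter$half_angle)^2 / (3 * pi^2)) * h_max^3
  } else {
    h_c <- h_max / 2
    pi * indenter$radius * h_c^2
  }
}

#' Full contact state at a given depth
#'
#' Evaluates the closed-form contact quantities for an elastic half-space at
#' maximum depth `h_max`: contact depth h_c, contact radius r_c, contact
#' stiffness S and contact volume V, as a one-row tibble. Useful for checking
#' the universal relation S / r_c = 2 E / (1 - nu^2).
#'
#' @inheritParams contact_volume
#' @param E Young's modulus in Pa.
#' @param nu Poisson's ratio.
#' @return A one-row tibble with columns `h_max`, `b`, `h_c`, `a`, `m`, `c`,
#'   `r_c`, `S`, `V` (SI units).
#' @export
contact_state <- function(indenter, E, nu = 0.5, h_max) {
  assert_indenter(indenter)
  stopifnot(length(h_max) == 1L, h_max > 0)
  assert_elastic(E, nu)
  m <- power_law_exponent(indenter)
  a <- if (is_cone(indenter)) {
    sneddon_prefactor(E, indenter, nu)
  } else {
    hertz_sphere_prefactor(E, indenter, nu)
  }
  b <- geometric_b(indenter)
  h_c <- h_max / b
  cc <- contact_radius_coefficient(a, m, E, nu, b)
  tibble::tibble(
    h_max = h_max, b = b, h_c = h_c, a = a, m = m, c = cc,
    r_c = cc * h_c^(m - 1),
    S = contact_stiffness(a, m, h_max),
    V = contact_volume(indenter, h_max)
  )
}
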