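#' Simulate a raw Hertzian (Sneddon) force curve
#'
#' Generates a synthetic raw AFM approach curve for a linear elastic
#' half-space probed by a conical tip, emulating a typical soft-cell
#' experiment: Sneddon forward model P = a h^2, the standard instrument
#' identities z = z0 + h + P/k (piezo travel = indentation + cantilever
#' bending) and d = P/k, a flat pre-contact baseline, and seeded zero-mean
#' Gaussian force noise added to the measured deflection.
#'
#' Defaults state the reference experiment: a 25-degree conical tip, a
#' 0.01 N/m cantilever, nu = 0.5, ~1000 nm maximum depth, and force noise
#' with SD equal to 1% of the maximum load.
#'
#' @param E Young's modulus in Pa.
#' @param indenter An [indenter_cone()]; the generator is conical.
#' @param nu Poisson's ratio, default 0.5.
#' @param k Cantilever spring constant in N/m, default 0.01.
#' @param h_max Maximum indentation depth in metres, default 1000 nm.
#' @param n_points Post-contact samples, default 1000.
#' @param pre_contact Baseline span in metres before contact, default 500 nm.
#' @param z0 Piezo position of first contact; defaults to `pre_contact` so
#'   the record starts at z = 0.
#' @param noise Relative force-noise SD as a fraction of P(h_max), default
#'   0.01. Set 0 for noise-free curves.
#' @param noise_absolute Absolute force-noise SD in newtons; overrides
#'   `noise` when given.
#' @param seed Integer seed fixing every random draw; `NULL` uses the
#'   current RNG state.
#' @return A [force_curve()] whose `metadata` carries the ground truth
#'   (`E`, `a`, `z0`, `h_max`, `noise_sd`, ...).
#' @examples
#' fc <- gen_hertzian_raw(E = 5160, seed = 1)
#' @export
gen_hertzian_raw <- function(E, indenter = indenter_cone(25), nu = 0.5,
                             k = 0.01, h_max = 1000e-9, n_points = 1000L,
                             pre_contact = 500e-9, z0 = NULL,
                             noise = 0.01, noise_absolute = NULL, seed = NULL) {
  assert_indenter(indenter)
  if (!is_cone(indenter)) stop("the generator is conical", call. = FALSE)
  a <- sneddon_prefactor(E, indenter, nu)
  gen_raw_from_load(
    load_fun = function(h) a * h^2,
    truth = list(
      model = "hertzian", E = E, nu = nu, a = a,
      half_angle = indenter$half_angle
    ),
    k = k, h_max = h_max, n_points = n_points, pre_contact = pre_contact,
    z0 = z0, noise = noise, noise_absolute = noise_absolute, seed = seed
  )
}

#' Simulate a depth-dependent raw force curve
#'
#' Two generating mechanisms for non-Hertzian behaviour:
#' * `mode = "quartic"`: P = a1 h^2 + a2 h^4, a smooth stiffening law whose
#'   work is a quadratic in x = h^3 plus a correction, exercising the
#'   polynomial fit;
#' * `mode = "bilayer"`: a soft layer over a stiffer base. The pointwise
#'   effective modulus follows a logistic transition
#'   E(h) = E_surface + (E_deep - E_surface) / (1 + exp(-(h - onset)/width))
#'   and P(h) = (2/pi) E(h) tan(theta) h^2 / (1 - nu^2), emulating substrate
#'   feel-through with a single onset knob.
#'
#' The instrument layer (baseline, conversion, noise) is identical to
#' [gen_hertzian_raw()].
#'
#' @inheritParams gen_hertzian_raw
#' @param mode `"quartic"` or `"bilayer"`.
#' @param E Surface Young's modulus in Pa (quartic mode uses it for a1).
#' @param a2 Quartic coefficient in N/m^4 (quartic mode).
#' @param E_deep Deep-layer modulus in Pa (bilayer mode).
#' @param onset Bilayer transition depth in metres, default 400 nm.
#' @param width Logistic transition width in metres, default 25 nm (a
#'   sharp interface on the scale of the layer: roughly 6% of the default
#'   onset depth).
#' @return A [force_curve()] with ground truth in `metadata`.
#' @export
gen_depth_dependent_raw <- function(E, mode = c("quartic", "bilayer"),
                                    a2 = NULL, E_deep = NULL,
                                    onset = 400e-9, width = 25e-9,
                                    indenter = indenter_cone(25), nu = 0.5,
                                    k = 0.01, h_max = 1000e-9,
                                    n_points = 1000L, pre_contact = 500e-9,
                                    z0 = NULL, noise = 0.01,
                                    noise_absolute = NULL, seed = NULL) {
  assert_indenter(indenter)
  if (!is_cone(indenter)) stop("the generator is conical", call. = FALSE)
  mode <- match.arg(mode)
  a1 <- sneddon_prefactor(E, indenter, nu)
  if (mode == "quartic") {
    if (is.null(a2)) stop("quartic mode needs `a2`", call. = FALSE)
    load_fun <- function(h) a1 * h^2 + a2 * h^4
    truth <- list(
      model = "quartic", E = E, nu = nu, a1 = a1, a2 = a2,
      half_angle = indenter$half_angle
    )
  } else {
    if (is.null(E_deep)) stop("bilayer mode needs `E_deep`", call. = FALSE)
    stopifnot(onset > 0, width > 0)
    theta <- indenter$half_angle
    load_fun <- function(h) {
      E_eff <- E + (E_deep - E) / (1 + exp(-(h - onset) / width))
      (2 / pi) * E_eff * tan(theta) / (1 - nu^2) * h^2
    }
    truth <- list(
      model = "bilayer", E_surface = E, E_deep = E_deep, nu = nu,
      onset = onset, width = width, half_angle = indenter$half_angle
    )
  }
  gen_raw_from_load(
    load_fun = load_fun, truth = truth,
    k = k, h_max = h_max, n_points = n_points, pre_contact = pre_contact,
    z0 = z0, noise = noise, noise_absolute = noise_absolute, seed = seed
  )
}

# shared instrument layer: baseline + conversion + seeded force noise
gen_raw_from_load <- function(load_fun, truth, k, h_max, n_points,
                              pre_contact, z0, noise, noise_absolute, seed) {
  stopifnot(k > 0, h_max > 0, n_points >= 20L, pre_contact > 0)
  if (is.null(z0)) z0 <- pre_contact
  h <- seq(0, h_max, length.out = n_points)
  P <- load_fun(h)
  z_post <- z0 + h + P / k
  d_post <- P / k
  step <- h_max / (n_points - 1)
  n_pre <- max(20L, ceiling(pre_contact / step))
  z_pre <- seq(z0 - pre_contact, z0, length.out = n_pre + 1L)[-(n_pre + 1L)]
  z <- c(z_pre, z_post)
  d <- c(rep(0, n_pre), d_post)
  sd_F <- if (!is.null(noise_absolute)) noise_absolute else noise * max(P)
  make_noisy <- function() {
    dn <- if (sd_F > 0) d + stats::rnorm(length(d), sd = sd_F) / k else d
    force_curve(z, dn, k, metadata = c(truth, list(
      z0 = z0, d0 = 0, h_max = h_max, n_points = n_points,
      pre_contact = pre_contact, noise_sd_N = sd_F, seed = seed
    )))
  }
  if (!is.null(seed)) withr::with_seed(seed, make_noisy()) else make_noisy()
}

#' Simulate a force-volume grid
#'
#' Generates one synthetic raw curve per pixel of an AFM force-volume scan,
#' with per-pixel ground-truth moduli drawn independently from a stated
#' distribution. Defaults emulate a typical cell map: an 8 x 8 grid over a
#' 12.5 um x 12.5 um region with lognormal moduli of mean 7.4 kPa and SD
#' 2 kPa.
#'
#' @param n_rows,n_cols Grid dimensions, default 8 x 8.
#' @param E_mean,E_sd Natural-scale mean and SD of the pixel modulus in Pa.
#' @param distribution `"lognormal"` (default; positive, right-skewed, the
#'   usual shape of cell-modulus maps) or `"constant"` (every pixel at
#'   `E_mean`).
#' @param region Physical side length of the scan region in metres, default
#'   12.5 um.
#' @param seed Integer seed; every random draw (moduli and per-curve noise)
#'   flows from it.
#' @param ... Further arguments passed to [gen_hertzian_raw()] (noise,
#'   depth, point count, ...).
#' @return A list with `curves` (row-major list of [force_curve()]s),
#'   `truth` (tibble: `row`, `col`, `x_um`, `y_um`, `E_true_Pa`) and
#'   `layout` (list with `n_rows`, `n_cols`, `pixel_size`).
#' @export
gen_grid <- function(n_rows = 8L, n_cols = 8L, E_mean = 7.4e3, E_sd = 2e3,
                     distribution = c("lognormal", "constant"),
                     region = 12.5e-6, seed = NULL, ...) {
  distribution <- match.arg(distribution)
  stopifnot(n_rows >= 1L, n_cols >= 1L, E_mean > 0, E_sd >= 0, region > 0)
  n <- n_rows * n_cols
  pixel_size <- region / max(n_rows, n_cols)
  run <- function() {
    E_true <- if (distribution == "constant" || E_sd == 0) {
      rep(E_mean, n)
    } else {
      sdlog <- sqrt(log(1 + (E_sd / E_mean)^2))
      meanlog <- log(E_mean) - sdlog^2 / 2
      stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    }
    idx <- tidyr::expand_grid(row = seq_len(n_rows) - 1L, col = seq_len(n_cols) - 1L)
    curves <- purrr::map(seq_len(n), function(i) {
      fc <- gen_hertzian_raw(E = E_true[i], seed = NULL, ...)
      md <- attr(fc, "metadata")
      md$row <- idx$row[i]
      md$col <- idx$col[i]
      attr(fc, "metadata") <- md
      fc
    })
    truth <- dplyr::mutate(idx,
      x_um = (.data$col + 0.5) * pixel_size * 1e6,
      y_um = (.data$row + 0.5) * pixel_size * 1e6,
      E_true_Pa = E_true
    )
    list(
      curves = curves, truth = truth,
      layout = list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size)
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
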