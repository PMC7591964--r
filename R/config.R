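#' Analysis configuration
#'
#' Bundles every tunable of the per-curve pipeline. Angles are taken in
#' degrees at this boundary and converted to radians internally; all lengths
#' are metres, forces newtons, moduli pascals.
#'
#' @param half_angle Cone half-angle in degrees, default 25 (a common
#'   sharp-pyramid effective angle).
#' @param nu Poisson's ratio, default 0.5 (incompressible, the usual cell
#'   assumption).
#' @param k Cantilever spring constant in N/m, default 0.01.
#' @param depth_limit Optional analysis depth limit in metres (e.g. 200e-9
#'   to restrict to the first 200 nm); `NULL` uses the full curve.
#' @param linearity_threshold R^2 threshold of the W = f(h^3) test, default
#'   0.999.
#' @param contact_method `"piecewise"` or `"threshold"`, see
#'   [find_contact_point()].
#' @param spherical_printed_form Use the pi-free spherical W/V variant, see
#'   [wv_spherical()]. Default `FALSE`.
#' @param thickness Optional sample thickness in metres; when given,
#'   indentation beyond 10% of it triggers a substrate warning (Buckle's
#'   rule).
#' @param floor_frac W/V profile depth floor, default 0.05.
#' @param seed Optional integer seed for stochastic subcommands.
#' @return A list of class `afmwv_config`.
#' @export
analysis_config <- function(half_angle = 25, nu = 0.5, k = 0.01,
                            depth_limit = NULL, linearity_threshold = 0.999,
                            contact_method = c("piecewise", "threshold"),
                            spherical_printed_form = FALSE, thickness = NULL,
                            floor_frac = 0.05, seed = NULL) {
  contact_method <- match.arg(contact_method)
  stopifnot(half_angle > 0, half_angle < 90, nu >= 0, nu <= 0.5, k > 0)
  if (!is.null(depth_limit)) stopifnot(depth_limit > 0)
  structure(
    list(
      half_angle = half_angle, nu = nu, k = k, depth_limit = depth_limit,
      linearity_threshold = linearity_threshold,
      contact_method = contact_method,
      spherical_printed_form = spherical_printed_form,
      thickness = thickness, floor_frac = floor_frac, seed = seed
    ),
    class = "afmwv_config"
  )
}

config_indenter <- function(config) indenter_cone(config$half_angle)

#' Read and write configuration files
#'
#' Configurations serialise to JSON and round-trip exactly:
#' `read_config(write_config(cfg, path))` reproduces `cfg`.
#'
#' @param config An [analysis_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the configuration.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "afmwv_config"))
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}
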