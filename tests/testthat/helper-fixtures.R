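# shared fixtures: the reference experiment is a 25-degree conical tip on a
# fibroblast-like sample (E ~ 5 kPa, nu = 0.5, k = 0.01 N/m)

cone25 <- indenter_cone(25)

# noise-free power-law load-indentation curve P = a h^m on a uniform grid
make_power_curve <- function(a, m = 2, h_max = 1149e-9, n = 1000L) {
  h <- seq(0, h_max, length.out = n)
  indentation_curve(h, a * h^m)
}

# contact point constructed from generator ground truth (exact z0, d0 = 0)
true_contact_point <- function(fc) {
  md <- attr(fc, "metadata")
  idx <- which.min(abs(fc$z - md$z0))
  structure(
    list(
      index = idx, z0 = md$z0, d0 = 0, tilt_slope = 0,
      method = "truth", quality = 1
    ),
    class = "contact_point"
  )
}

# grid-step error of the detected contact point against generator truth
cp_step_error <- function(fc, ...) {
  md <- attr(fc, "metadata")
  find_contact_point(fc, ...)$index - which.min(abs(fc$z - md$z0))
}

# minimal hand-built map_grid for summary tests
fake_map <- function(E_fit, status = rep("ok", length(E_fit))) {
  n <- length(E_fit)
  out <- tibble::tibble(
    row = rep(0L, n), col = seq_len(n) - 1L, x_um = NA_real_, y_um = NA_real_,
    E_fit_Pa = E_fit, E_wv_Pa = E_fit, wv_mean_Jm3 = E_fit,
    r2_fit = 1, r2_linearity = 1, is_linear = TRUE,
    h_max_used_m = 1e-6, status = status
  )
  attr(out, "n_rows") <- 1L
  attr(out, "n_cols") <- n
  attr(out, "pixel_size") <- NULL
  class(out) <- c("map_grid", class(out))
  out
}
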