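#' Analyse one raw force curve end to end
#'
#' Runs the full per-curve pipeline: contact-point detection, conversion to a
#' load-indentation curve, optional depth truncation, cumulative work, the
#' W = f(h^3) linearity test, a Sneddon fit, and the W/V modulus route. When
#' the curve passes the linearity test both modulus estimates are reported;
#' when it fails, the modulus from W/V is withheld (Hertzian analysis is
#' invalid) and the mean W/V ratio plus the depth-dependent polynomial
#' describe the pixel instead.
#'
#' The function never raises on a bad curve: failures are captured in the
#' `status` field (`"ok"`, `"no_contact"`, `"fit_failed"`).
#'
#' @param curve A [force_curve()].
#' @param config An [analysis_config()].
#' @param detail Also return the intermediate objects (fit, profile,
#'   polynomial) as a list? Default `FALSE`.
#' @return A one-row tibble with `row`, `col` (grid indices when known, else
#'   `NA`), `E_fit_Pa`, `E_wv_Pa`, `wv_mean_Jm3`, `r2_fit`, `r2_linearity`,
#'   `is_linear`, `h_max_used_m`, `status`. With `detail = TRUE`, a list
#'   `(result, indentation, work, wv, fit, linearity, poly)`.
#' @export
analyze_curve <- function(curve, config = analysis_config(), detail = FALSE) {
  stopifnot(inherits(curve, "force_curve"), inherits(config, "afmwv_config"))
  md <- attr(curve, "metadata")
  base <- tibble::tibble(
    row = md$row %||% NA_integer_, col = md$col %||% NA_integer_,
    E_fit_Pa = NA_real_, E_wv_Pa = NA_real_, wv_mean_Jm3 = NA_real_,
    r2_fit = NA_real_, r2_linearity = NA_real_, is_linear = NA,
    h_max_used_m = NA_real_, status = "ok"
  )
  indenter <- config_indenter(config)
  objs <- list()
  res <- tryCatch(
    {
      cp <- find_contact_point(curve, method = config$contact_method)
      ic <- to_indentation(curve, cp)
      if (!is.null(config$depth_limit)) {
        ic <- truncate_depth(ic, config$depth_limit)
      }
      h_max <- max(ic$h)
      check_buckle(h_max, config$thickness)
      wp <- work_numeric(ic)
      lin <- linearity_test(wp, config$linearity_threshold)
      fit <- fit_sneddon(ic, indenter, config$nu)
      wvp <- wv_profile(wp, indenter, config$floor_frac)
      wv_mean <- mean(wvp$wv)
      out <- base
      out$E_fit_Pa <- fit$E
      out$r2_fit <- fit$r_squared
      out$r2_linearity <- lin$r_squared
      out$is_linear <- lin$is_linear
      out$wv_mean_Jm3 <- wv_mean
      out$h_max_used_m <- h_max
      if (lin$is_linear) {
        # modulus from the endpoint ratio W(h_max)/V(h_max): the full-depth
        # work integral averages the force noise away, whereas the profile
        # mean weights the noise-amplified shallow ratios equally
        wv_end <- wp$W[nrow(wp)] / contact_volume(indenter, h_max)
        out$E_wv_Pa <- E_from_wv(wv_end, indenter, config$nu)
        objs$poly <- NULL
      } else {
        objs$poly <- tryCatch(fit_wv_polynomial(wp), error = function(e) NULL)
      }
      objs$indentation <- ic
      objs$work <- wp
      objs$wv <- wvp
      objs$fit <- fit
      objs$linearity <- lin
      out
    },
    error = function(e) {
      out <- base
      out$status <- if (grepl("no contact", conditionMessage(e))) {
        "no_contact"
      } else {
        "fit_failed"
      }
      out
    }
  )
  if (detail) c(list(result = res), objs) else res
}

#' Analyse a grid of force curves into a mechanical-property map
#'
#' Applies [analyze_curve()] to every curve of a force-volume acquisition in
#' a deterministic row-major order (top-left origin; serpentine rasters are
#' handled by `serpentine = TRUE`, which reverses every odd row).
#'
#' @param curves List of [force_curve()]s, length `n_rows * n_cols`.
#' @param n_rows,n_cols Grid dimensions.
#' @param pixel_size Pixel pitch in metres (e.g. `12.5e-6 / 8`); used for the
#'   physical `x_um`/`y_um` coordinates.
#' @param config An [analysis_config()].
#' @param serpentine Curves were acquired in serpentine order?
#' @return A tibble of class `map_grid`, one row per pixel, with grid
#'   indices, physical coordinates in micrometres, and the [analyze_curve()]
#'   fields. Grid metadata is carried in attributes `n_rows`, `n_cols`,
#'   `pixel_size`.
#' @export
analyze_grid <- function(curves, n_rows, n_cols, pixel_size = NULL,
                         config = analysis_config(), serpentine = FALSE) {
  stopifnot(is.list(curves), n_rows >= 1L, n_cols >= 1L)
  n <- n_rows * n_cols
  if (length(curves) != n) {
    stop(sprintf(
      "layout mismatch: %d curves for a %d x %d grid", length(curves),
      n_rows, n_cols
    ), call. = FALSE)
  }
  idx <- tidyr::expand_grid(row = seq_len(n_rows) - 1L, col = seq_len(n_cols) - 1L)
  if (serpentine) {
    idx <- dplyr::mutate(idx,
      col = ifelse(.data$row %% 2L == 1L, n_cols - 1L - .data$col, .data$col)
    )
  }
  px <- purrr::map(seq_len(n), function(i) {
    r <- analyze_curve(curves[[i]], config)
    r$row <- idx$row[i]
    r$col <- idx$col[i]
    r
  })
  out <- dplyr::bind_rows(px)
  ps_um <- if (is.null(pixel_size)) NA_real_ else pixel_size * 1e6
  out <- dplyr::mutate(out,
    x_um = (.data$col + 0.5) * ps_um,
    y_um = (.data$row + 0.5) * ps_um,
    .after = "col"
  )
  attr(out, "n_rows") <- n_rows
  attr(out, "n_cols") <- n_cols
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("map_grid", class(out))
  out
}

#' Summary statistics of a mechanical-property map
#'
#' Mean, sample (n-1) standard deviation, pixel count and a histogram of one
#' mapped field, computed over `status == "ok"` pixels only. Pixels failing
#' the linearity test carry no `E_wv_Pa` (the modulus route is invalid
#' there) and are therefore excluded from its distribution automatically,
#' while still contributing to W/V summaries.
#'
#' @param map A `map_grid` from [analyze_grid()].
#' @param field `"E_fit_Pa"`, `"E_wv_Pa"` or `"wv_mean_Jm3"`.
#' @param bins Histogram bin count, default 10.
#' @return A list with `field`, `mean`, `sd`, `n` and `histogram` (tibble
#'   with `mid`, `count`).
#' @export
summarize_map <- function(map, field = c("E_fit_Pa", "E_wv_Pa", "wv_mean_Jm3"),
                          bins = 10L) {
  stopifnot(inherits(map, "map_grid"))
  field <- match.arg(field)
  vals <- map[[field]][map$status == "ok"]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) {
    stop(sprintf("no ok pixels carry %s", field), call. = FALSE)
  }
  hh <- graphics::hist(vals, breaks = bins, plot = FALSE)
  list(
    field = field,
    mean = mean(vals),
    sd = if (length(vals) > 1L) stats::sd(vals) else 0,
    n = length(vals),
    histogram = tibble::tibble(mid = hh$mids, count = hh$counts)
  )
}

#' Export a map as TSV / JSON
#'
#' `write_map_tsv()` writes one row per pixel with explicit units in every
#' column name; `write_map_summary_json()` writes the [summarize_map()]
#' statistics for each available field.
#'
#' @param map A `map_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "map_grid"))
  cols <- c(
    "row", "col", "x_um", "y_um", "E_fit_Pa", "E_wv_Pa", "wv_mean_Jm3",
    "r2_fit", "r2_linearity", "is_linear", "h_max_used_m", "status"
  )
  utils::write.table(as.data.frame(map)[, cols], path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
write_map_summary_json <- function(map, path) {
  stopifnot(inherits(map, "map_grid"))
  fields <- c("E_fit_Pa", "E_wv_Pa", "wv_mean_Jm3")
  summaries <- list()
  for (f in fields) {
    s <- tryCatch(summarize_map(map, f), error = function(e) NULL)
    if (!is.null(s)) {
      summaries[[f]] <- list(mean = s$mean, sd = s$sd, n = s$n)
    }
  }
  summaries$n_pixels <- nrow(map)
  summaries$n_ok <- sum(map$status == "ok")
  jsonlite::write_json(summaries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
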