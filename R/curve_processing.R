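#' Convert cantilever deflection to force
#'
#' Hooke's law for the cantilever: P = k (d - d0), with `d0` the baseline
#' deflection.
#'
#' @param d Cantilever deflection in metres (vectorised).
#' @param k Spring constant in N/m, > 0.
#' @param d0 Baseline deflection in metres, default 0.
#' @return Force in newtons.
#' @export
deflection_to_force <- function(d, k, d0 = 0) {
  stopifnot(is.numeric(d), is.numeric(k), length(k) == 1L)
  if (k <= 0) stop("spring constant must be > 0", call. = FALSE)
  k * (d - d0)
}

#' Locate the contact point of a raw force curve
#'
#' Estimates the sample at which the tip first touches the surface. The
#' default `"piecewise"` method performs piecewise model selection: for every
#' candidate split z0 the curve is modelled as a constant baseline before z0
#' and a quadratic in (z - z0) after it, and the split minimising the total
#' squared residual wins. The `quality` score is the relative residual
#' improvement over the no-contact (flat) model; splits that do not improve
#' on the flat model by at least `min_quality` raise a "no contact detected"
#' error. The `"threshold"` alternative takes the first sample whose
#' deflection exceeds the baseline mean by `n_sd` baseline standard
#' deviations.
#'
#' A linear tilt in the baseline (a common AFM artifact) is removed when the
#' baseline slope is statistically significant (t-test p < 0.01); the fitted
#' slope is carried on the result and applied by [to_indentation()].
#'
#' @param curve A [force_curve()] with a pre-contact baseline of at least
#'   `min_baseline` points.
#' @param method `"piecewise"` (default) or `"threshold"`.
#' @param min_baseline Minimum number of baseline points, default 10.
#' @param n_sd Threshold-method multiplier, default 5.
#' @param min_quality Minimum relative residual improvement for the
#'   piecewise method to accept a contact, default 0.2.
#' @return An object of class `contact_point`: list with `index`, `z0`,
#'   `d0` (m), `tilt_slope` (dimensionless), `method` and `quality`.
#' @export
find_contact_point <- function(curve, method = c("piecewise", "threshold"),
                               min_baseline = 10L, n_sd = 5,
                               min_quality = 0.2) {
  stopifnot(inherits(curve, "force_curve"))
  method <- match.arg(method)
  z <- curve$z
  d <- curve$d
  n <- length(z)
  if (n < min_baseline + 4L) {
    stop("curve too short for contact-point detection", call. = FALSE)
  }
  locate <- function(dd) {
    if (method == "piecewise") {
      piecewise_refined(z, dd, min_baseline, min_quality)
    } else {
      base <- dd[seq_len(min_baseline)]
      mu <- mean(base)
      sdv <- stats::sd(base)
      lim <- if (sdv > 0) mu + n_sd * sdv else mu
      hits <- which(dd > lim)
      hits <- hits[hits > min_baseline]
      if (length(hits) == 0L) stop("no contact detected", call. = FALSE)
      list(index = hits[1], quality = NA_real_)
    }
  }
  # significant baseline slope (photodiode tilt) is removed and the contact
  # point relocated on the corrected signal: the split models assume a flat
  # baseline and a tilted one biases the first pass
  baseline_tilt <- function(index) {
    base_idx <- seq_len(max(index - 1L, min_baseline))
    zb <- z[base_idx]
    db <- d[base_idx]
    if (length(base_idx) >= 5L && stats::var(zb) > 0) {
      fit <- stats::lm(db ~ zb)
      p <- summary(fit)$coefficients
      if (nrow(p) == 2L && !is.na(p[2, 4]) && p[2, 4] < 0.01) {
        return(unname(p[2, 1]))
      }
    }
    0
  }
  loc <- locate(d)
  tilt <- baseline_tilt(loc$index)
  if (tilt != 0) {
    loc <- locate(d - tilt * (z - z[loc$index]))
    tilt <- baseline_tilt(loc$index)
  }
  index <- loc$index
  base_idx <- seq_len(max(index - 1L, min_baseline))
  d0 <- mean(d[base_idx] - tilt * (z[base_idx] - z[index]))
  structure(
    list(
      index = index, z0 = z[index], d0 = d0, tilt_slope = tilt,
      method = method, quality = loc$quality
    ),
    class = "contact_point"
  )
}

# minimise SS(baseline const on 1..i) + SS(post-contact Sneddon-quadratic on
# i..n) over candidate splits i. The post model is quadratic in the candidate
# indentation h = (z - z[i]) - (d - d0), not in (z - z[i]): with soft
# cantilevers the bending term P/k is comparable to h and a quadratic in piezo
# travel alone biases the split towards the baseline. Coarse stride then
# single-step refinement keeps the scan O(n * n/stride) on long curves.
# On strongly depth-dependent curves the quadratic post model under-fits the
# deep stiffening and drags the split towards the baseline, always LATE.
# Re-running the split on a shallow truncated sub-curve (where the quadratic
# contact model is locally valid) corrects that lateness. The first
# acceptance margin is strict so that noise on genuinely Hertzian curves
# cannot trigger a spurious shift; once a real shift is confirmed the
# remaining iterations converge with a tight margin.
piecewise_refined <- function(z, d, min_baseline, min_quality) {
  n <- length(z)
  cur <- piecewise_split(z, d, min_baseline, min_quality)
  # refine only on evidence of model mismatch: for a Hertzian curve the
  # post-contact residual is pure noise, the same size as the baseline
  # residual; systematic under-fitting inflates it well beyond that
  if (cur$mse_post <= 4 * cur$mse_base + .Machine$double.eps) {
    return(cur)
  }
  margin <- max(20L, ceiling(0.05 * (n - cur$index)))
  for (it in 1:4) {
    n_post <- n - cur$index
    hi <- min(n, cur$index + max(50L, ceiling(0.25 * n_post)))
    if (hi - min_baseline < 30L) break
    new <- tryCatch(
      piecewise_split(z[1:hi], d[1:hi], min_baseline, min_quality = 0),
      error = function(e) NULL
    )
    if (is.null(new) || new$index >= cur$index - margin) break
    cur$index <- new$index
    margin <- 5L
  }
  cur
}

piecewise_split <- function(z, d, min_baseline, min_quality) {
  n <- length(z)
  ss_flat <- sum((d - mean(d))^2)
  if (ss_flat == 0) stop("no contact detected", call. = FALSE)
  cand <- seq(min_baseline, n - 4L)
  stride <- max(1L, floor(length(cand) / 400L))
  coarse <- cand[seq(1L, length(cand), by = stride)]
  eval_split <- function(i, parts = FALSE) {
    mu <- mean(d[1:i])
    ss1 <- sum((d[1:i] - mu)^2)
    y <- d[i:n] - mu
    hcand <- (z[i:n] - z[i]) - y
    h2 <- pmax(hcand, 0)^2
    s4 <- sum(h2 * h2)
    beta <- if (s4 > 0) max(0, sum(y * h2) / s4) else 0
    ss2 <- sum((y - beta * h2)^2)
    if (parts) c(ss1, ss2) else ss1 + ss2
  }
  ss <- vapply(coarse, eval_split, numeric(1))
  best <- coarse[which.min(ss)]
  if (stride > 1L) {
    fine <- seq(max(min_baseline, best - stride), min(n - 4L, best + stride))
    ssf <- vapply(fine, eval_split, numeric(1))
    best <- fine[which.min(ssf)]
    ss_best <- min(ssf)
  } else {
    ss_best <- min(ss)
  }
  quality <- 1 - ss_best / ss_flat
  if (!is.finite(quality) || quality < min_quality) {
    stop("no contact detected", call. = FALSE)
  }
  pp <- eval_split(best, parts = TRUE)
  list(
    index = best, quality = quality,
    mse_base = pp[1] / best, mse_post = pp[2] / (n - best + 1L)
  )
}

#' Convert a raw force curve to a load-indentation curve
#'
#' Applies the standard AFM identity: indentation depth
#' h = (z - z0) - (d - d0) and load P = k (d - d0), restricted to the
#' post-contact segment. Any baseline tilt detected by
#' [find_contact_point()] is removed first. Deflection noise makes the
#' computed depth locally non-monotone; the (h, P) pairs are reordered by
#' depth (raw values are preserved rather than smoothed, and no sample is
#' discarded), so the output depth is strictly increasing.
#'
#' @param curve A [force_curve()].
#' @param cp A `contact_point` from [find_contact_point()]; located
#'   automatically when omitted.
#' @param ... Passed to [find_contact_point()] when `cp` is missing.
#' @return An [indentation_curve()] (tibble with `h`, `P`).
#' @export
to_indentation <- function(curve, cp = NULL, ...) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(cp)) cp <- find_contact_point(curve, ...)
  stopifnot(inherits(cp, "contact_point"))
  n <- nrow(curve)
  if (cp$index < 1L || cp$index > n) {
    stop("contact point index outside the curve", call. = FALSE)
  }
  seg <- seq(cp$index, n)
  z <- curve$z[seg]
  d <- curve$d[seg] - cp$tilt_slope * (curve$z[seg] - cp$z0)
  dd <- d - cp$d0
  P <- deflection_to_force(d, spring_constant(curve), cp$d0)
  h <- (z - cp$z0) - dd
  keep <- h >= 0
  h <- h[keep]
  P <- P[keep]
  # Deflection noise enters both channels (P = k dd, h = zz - dd), so noisy
  # depth is locally non-monotone. Reorder the (h, P) pairs by depth instead
  # of dropping backward samples: dropping selects against positive force
  # noise and biases every downstream estimate low, while reordering keeps
  # all raw values. Exact depth ties (measure zero under noise) are merged
  # by averaging their loads.
  if (length(h) > 1L) {
    o <- order(h)
    h <- h[o]
    P <- P[o]
    if (anyDuplicated(h)) {
      P <- as.numeric(tapply(P, match(h, unique(h)), mean))
      h <- unique(h)
    }
  }
  if (length(h) < 4L) {
    stop("post-contact segment has fewer than 4 usable points", call. = FALSE)
  }
  indentation_curve(h, P, metadata = attr(curve, "metadata"))
}

#' Truncate a load-indentation curve at a depth limit
#'
#' Keeps all samples with h <= `h_limit`, preserving order. Shallow-depth
#' truncation is the standard guard against substrate effects when only the
#' near-surface response is of interest (e.g. the first 200 nm).
#'
#' @param curve An [indentation_curve()].
#' @param h_limit Depth limit in metres, > 0.
#' @return The truncated [indentation_curve()].
#' @export
truncate_depth <- function(curve, h_limit) {
  stopifnot(inherits(curve, "indentation_curve"))
  stopifnot(is.numeric(h_limit), length(h_limit) == 1L)
  if (h_limit <= 0) stop("h_limit must be > 0", call. = FALSE)
  keep <- curve$h <= h_limit
  if (sum(keep) < 4L) {
    stop("fewer than 4 points survive the depth limit", call. = FALSE)
  }
  indentation_curve(curve$h[keep], curve$P[keep],
    metadata = attr(curve, "metadata")
  )
}
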