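#' Raw AFM force curve
#'
#' A raw approach record from an AFM force-spectroscopy experiment: piezo
#' displacement `z` and cantilever deflection `d`, both in metres, together
#' with the cantilever spring constant `k` in N/m. The tip approaches the
#' surface with increasing `z`; everything before the contact point is
#' baseline.
#'
#' @param z Piezo displacement in metres, approach direction (increasing).
#' @param d Cantilever deflection in metres.
#' @param spring_constant Cantilever spring constant k in N/m, > 0.
#' @param metadata Free-form provenance list (file path, grid position, ...).
#' @return A tibble of class `force_curve` with columns `z` and `d` and
#'   attributes `spring_constant` and `metadata`.
#' @export
force_curve <- function(z, d, spring_constant, metadata = list()) {
  stopifnot(is.numeric(z), is.numeric(d), length(z) == length(d))
  if (length(z) < 20L) {
    stop("a force curve needs at least 20 samples", call. = FALSE)
  }
  stopifnot(is.numeric(spring_constant), length(spring_constant) == 1L)
  if (spring_constant <= 0) stop("spring constant must be > 0", call. = FALSE)
  out <- tibble::tibble(z = as.numeric(z), d = as.numeric(d))
  attr(out, "spring_constant") <- as.numeric(spring_constant)
  attr(out, "metadata") <- metadata
  class(out) <- c("force_curve", class(out))
  out
}

#' @rdname force_curve
#' @param curve A `force_curve`.
#' @export
spring_constant <- function(curve) {
  k <- attr(curve, "spring_constant")
  if (is.null(k)) stop("object carries no spring constant", call. = FALSE)
  k
}

#' Load-indentation curve
#'
#' A processed curve of applied load `P` (N) against indentation depth `h`
#' (m), with the contact point removed: `h` starts at (or just above) zero
#' and increases strictly.
#'
#' @param h Indentation depth in metres: non-negative, strictly increasing.
#' @param P Applied load in newtons.
#' @param metadata Free-form provenance list.
#' @return A tibble of class `indentation_curve` with columns `h` and `P`.
#' @export
indentation_curve <- function(h, P, metadata = list()) {
  stopifnot(is.numeric(h), is.numeric(P), length(h) == length(P))
  if (length(h) < 4L) {
    stop("an indentation curve needs at least 4 samples", call. = FALSE)
  }
  if (any(h < 0)) stop("indentation depth must be non-negative", call. = FALSE)
  bad <- which(diff(h) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "indentation depth must be strictly increasing (first violation at index %d)",
      bad[1] + 1L
    ), call. = FALSE)
  }
  out <- tibble::tibble(h = as.numeric(h), P = as.numeric(P))
  attr(out, "metadata") <- metadata
  class(out) <- c("indentation_curve", class(out))
  out
}

# keep subclass + attributes through dplyr verbs used internally
reclass_curve <- function(new, template) {
  attr(new, "spring_constant") <- attr(template, "spring_constant")
  attr(new, "metadata") <- attr(template, "metadata")
  class(new) <- class(template)
  new
}
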