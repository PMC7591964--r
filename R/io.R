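#' Curve file dialect
#'
#' Describes how a delimited text file maps onto a curve: which two columns
#' it carries (raw `z`/`d` displacement-deflection, or processed `h`/`P`
#' load-indentation), their units, the delimiter, and where the spring
#' constant comes from. The native format written by [write_force_curve()]
#' declares everything in its header, so the default dialect reads it back
#' without configuration.
#'
#' @param columns `c("z", "d")` (raw) or `c("h", "P")` (processed).
#' @param units Length-2 character vector of per-column units:
#'   `"m"`, `"um"`, `"nm"` for lengths; `"N"`, `"nN"`, `"pN"` for force.
#' @param delim Field delimiter, default tab.
#' @param spring_constant Spring constant in N/m when the file header does
#'   not declare one (raw curves only).
#' @return A list of class `curve_dialect`.
#' @export
curve_dialect <- function(columns = c("z", "d"), units = c("m", "m"),
                          delim = "\t", spring_constant = NULL) {
  columns <- match.arg(paste(columns, collapse = ","), c("z,d", "h,P"))
  columns <- strsplit(columns, ",")[[1]]
  stopifnot(length(units) == 2L)
  structure(
    list(
      columns = columns, units = units, delim = delim,
      spring_constant = spring_constant
    ),
    class = "curve_dialect"
  )
}

unit_factor <- function(u) {
  f <- c(m = 1, um = 1e-6, nm = 1e-9, N = 1, nN = 1e-9, pN = 1e-12)[u]
  if (anyNA(f)) {
    stop(sprintf("unknown unit '%s'", u[is.na(f)][1]), call. = FALSE)
  }
  unname(f)
}

#' Write a curve to the native headered text format
#'
#' Writes a tab-separated file with a `#`-prefixed header block declaring
#' the column roles, units (always SI on write) and, for raw curves, the
#' spring constant — diff-able plain text rather than a vendor binary.
#'
#' @param curve A [force_curve()] or [indentation_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  if (inherits(curve, "force_curve")) {
    header <- c(
      "# afmwv curve",
      "# columns: z d",
      "# units: m m",
      sprintf("# spring_constant_N_per_m: %.17g", spring_constant(curve)),
      "z\td"
    )
    body <- sprintf("%.17g\t%.17g", curve$z, curve$d)
  } else if (inherits(curve, "indentation_curve")) {
    header <- c("# afmwv curve", "# columns: h P", "# units: m N", "h\tP")
    body <- sprintf("%.17g\t%.17g", curve$h, curve$P)
  } else {
    stop("not a curve object", call. = FALSE)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a curve from delimited text
#'
#' Reads the native headered format (self-describing) or any two-column
#' delimited file described by a [curve_dialect()]. All values are converted
#' to SI on read; provenance (path, dialect) is stored in the curve
#' metadata.
#'
#' @param path File path.
#' @param dialect A [curve_dialect()]; header declarations in the file
#'   override it.
#' @return A [force_curve()] (z/d dialects) or [indentation_curve()] (h/P
#'   dialects).
#' @export
read_force_curve <- function(path, dialect = curve_dialect()) {
  stopifnot(inherits(dialect, "curve_dialect"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop(sprintf("parse error in %s: empty file", path), call. = FALSE)
  }
  is_hdr <- grepl("^#", lines)
  header <- lines[is_hdr]
  # header declarations override the dialect
  get_hdr <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), header, value = TRUE)
    if (length(m) == 0L) {
      return(NULL)
    }
    trimws(sub(sprintf("^#\\s*%s:\\s*", key), "", m[1]))
  }
  cols <- get_hdr("columns")
  if (!is.null(cols)) dialect$columns <- strsplit(cols, "\\s+")[[1]]
  un <- get_hdr("units")
  if (!is.null(un)) dialect$units <- strsplit(un, "\\s+")[[1]]
  kh <- get_hdr("spring_constant_N_per_m")
  if (!is.null(kh)) dialect$spring_constant <- as.numeric(kh)
  body <- lines[!is_hdr]
  body_line_nos <- which(!is_hdr)
  # drop a column-name row if present
  if (length(body) > 0L && grepl("[A-Za-z]", body[1])) {
    body <- body[-1]
    body_line_nos <- body_line_nos[-1]
  }
  if (length(body) == 0L) {
    stop(sprintf("parse error in %s: no data rows", path), call. = FALSE)
  }
  parts <- strsplit(body, dialect$delim, fixed = TRUE)
  nums <- suppressWarnings(
    lapply(parts, function(p) as.numeric(p[nzchar(p)]))
  )
  bad <- which(vapply(nums, function(x) length(x) != 2L || anyNA(x), logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf(
      "parse error in %s at line %d: expected two numeric fields",
      path, body_line_nos[bad[1]]
    ), call. = FALSE)
  }
  m <- do.call(rbind, nums)
  f <- vapply(dialect$units, unit_factor, numeric(1))
  c1 <- m[, 1] * f[1]
  c2 <- m[, 2] * f[2]
  meta <- list(path = path, units = dialect$units)
  if (identical(dialect$columns, c("z", "d"))) {
    if (is.null(dialect$spring_constant)) {
      stop("dialect error: no spring constant in header or dialect", call. = FALSE)
    }
    force_curve(c1, c2, dialect$spring_constant, metadata = meta)
  } else {
    indentation_curve(c1, c2, metadata = meta)
  }
}
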