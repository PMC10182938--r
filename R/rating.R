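#' Construct a parameter rating curve
#'
#' A rating curve maps a raw parameter value (in its measurement unit) to a
#' dimensionless sub-index. The curve is piecewise linear over ordered
#' breakpoints; values outside the breakpoint domain are clamped to the
#' terminal sub-index (the curve is flat beyond its ends). NSFWQI sub-indices
#' live on \[0, 100\], IRWQISC sub-indices on \[1, 100\].
#'
#' @param parameter parameter key the curve rates (e.g. `"no3"`).
#' @param x numeric vector of breakpoint abscissae, strictly increasing.
#' @param q numeric vector of sub-index values at the breakpoints, same
#'   length as `x`, each in \[0, 100\].
#' @return an object of class `rating_curve`.
#' @seealso [rate_parameter()], [read_curves_csv()]
#' @export
rating_curve <- function(parameter, x, q) {
  stopifnot(is.character(parameter), length(parameter) == 1L)
  x <- as.numeric(x); q <- as.numeric(q)
  if (length(x) < 2L) stop("rating curve '", parameter, "' needs at least 2 breakpoints")
  if (length(x) != length(q)) stop("breakpoint x and q lengths differ for '", parameter, "'")
  if (anyNA(x) || anyNA(q)) stop("rating curve '", parameter, "' contains missing breakpoints")
  if (any(diff(x) <= 0)) stop("breakpoint x must be strictly increasing for '", parameter, "'")
  if (any(q < 0 | q > 100)) stop("sub-index breakpoints must lie in [0, 100] for '", parameter, "'")
  structure(list(parameter = parameter, x = x, q = q), class = "rating_curve")
}

#' @export
print.rating_curve <- function(x, ...) {
  cat("Rating curve for '", x$parameter, "': ", length(x$x),
      " breakpoints over [", x$x[1], ", ", x$x[length(x$x)], "]\n", sep = "")
  invisible(x)
}

#' Rate a raw parameter value on its curve
#'
#' Linear interpolation between the two breakpoints bracketing `value`;
#' values beyond the curve domain take the terminal breakpoint's sub-index.
#' This is the Q-value of the NSFWQI and the I-value of the IRWQISC.
#'
#' @param value numeric vector of raw values in the parameter's unit.
#' @param curve a [rating_curve()].
#' @return numeric vector of sub-indices.
#' @examples
#' cv <- rating_curve("demo", c(0, 100), c(100, 0))
#' rate_parameter(50, cv)   # 50
#' rate_parameter(250, cv)  # 0, clamped
#' @export
rate_parameter <- function(value, curve) {
  if (!inherits(curve, "rating_curve")) stop("'curve' must be a rating_curve")
  if (!is.numeric(value) || anyNA(value) || any(!is.finite(value)))
    stop("non-finite value passed to rate_parameter for '", curve$parameter, "'")
  stats::approx(curve$x, curve$q, xout = value, method = "linear", rule = 2)$y
}

#' Read a set of rating curves from CSV
#'
#' The file has columns `parameter,x,q`, rows grouped by parameter with `x`
#' ascending within each group (column order in the file is free; names are
#' matched). Returns a named list of [rating_curve()] objects.
#'
#' @param path path to the curves CSV.
#' @return named list of `rating_curve` objects, keyed by parameter.
#' @export
read_curves_csv <- function(path) {
  if (!file.exists(path)) stop("curves file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parameter", "x", "q")
  if (!all(need %in% names(df))) stop("curves CSV must have columns parameter,x,q: ", path)
  out <- lapply(split(df, df$parameter), function(g) {
    g <- g[order(g$x), , drop = FALSE]
    rating_curve(g$parameter[1], g$x, g$q)
  })
  out
}

#' Packaged default rating curves
#'
#' Returns the piecewise-linear curve tables shipped with the package for
#' the given scheme. These are best-effort encodings of the public NSF
#' Q-value curves and IRWQISC rating curves; the exact curves used in any
#' particular study are rarely published, so these tables are explicitly
#' replaceable via [read_curves_csv()]. Unit tests of the index engine use
#' synthetic curves and do not depend on these tables.
#'
#' @param scheme `"nsfwqi"` or `"irwqisc"`.
#' @return named list of `rating_curve` objects.
#' @export
default_curves <- function(scheme = c("nsfwqi", "irwqisc")) {
  scheme <- match.arg(scheme)
  f <- system.file("extdata",
                   if (scheme == "nsfwqi") "curves_nsfwqi.csv" else "curves_irwqisc.csv",
                   package = "wqrisk", mustWork = TRUE)
  read_curves_csv(f)
}
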