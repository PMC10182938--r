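#' Specify a marginal distribution for one stochastic model input
#'
#' Families:
#' \describe{
#'   \item{point}{degenerate mass at `value`}
#'   \item{uniform}{`min`, `max`}
#'   \item{triangular}{`min`, `mode`, `max` (inverse-CDF sampling)}
#'   \item{normal}{`mean`, `sd`; optional truncation `lower`/`upper`}
#'   \item{lognormal}{`meanlog`, `sdlog`; optional truncation `lower`/`upper`}
#'   \item{truncated_normal}{`mean`, `sd`, `lower`, `upper` (bounds required)}
#'   \item{empirical}{resamples `values` with replacement}
#' }
#' Truncation is exact (inverse-CDF on the restricted probability range),
#' not accept-reject, so draw counts are deterministic.
#'
#' @param family distribution family name (see above).
#' @param ... family parameters.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", meanlog = log(15), sdlog = 0.4, lower = 7.8, upper = 35.6)
#' @export
dist_spec <- function(family = c("point", "uniform", "triangular", "normal",
                                 "lognormal", "truncated_normal", "empirical"),
                      ...) {
  family <- match.arg(family)
  p <- list(...)
  num <- function(n) {
    v <- p[[n]]
    if (is.null(v)) stop("distribution family '", family, "' needs parameter '", n, "'")
    if (!is.numeric(v) || anyNA(v)) stop("parameter '", n, "' must be numeric")
    v
  }
  check_bounds <- function(lo, hi) if (lo >= hi) stop("truncation bounds must satisfy lower < upper")
  switch(family,
    point = num("value"),
    uniform = { if (num("min") > num("max")) stop("uniform needs min <= max") },
    triangular = {
      if (!(num("min") <= num("mode") && num("mode") <= num("max")))
        stop("triangular needs min <= mode <= max")
      if (num("min") == num("max")) stop("degenerate triangular; use a point mass")
    },
    normal = { if (num("sd") <= 0) stop("normal sd must be positive") },
    lognormal = { if (num("sdlog") <= 0) stop("lognormal sdlog must be positive") },
    truncated_normal = {
      if (num("sd") <= 0) stop("sd must be positive")
      check_bounds(num("lower"), num("upper"))
    },
    empirical = {
      v <- num("values")
      if (length(v) < 1L || any(!is.finite(v))) stop("empirical needs finite values")
    }
  )
  if (!is.null(p$lower) && !is.null(p$upper)) check_bounds(p$lower, p$upper)
  structure(c(list(family = family), p), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("dist_spec:", x$family, "(",
      paste(names(pars), vapply(pars, function(v) paste(signif(unlist(v), 4), collapse = ","),
                                character(1)), sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' @keywords internal
#' @noRd
sample_one <- function(spec, n) {
  lo <- spec$lower %||% -Inf
  hi <- spec$upper %||% Inf
  switch(spec$family,
    point = rep(spec$value, n),
    uniform = stats::runif(n, spec$min, spec$max),
    triangular = {
      a <- spec$min; c <- spec$mode; b <- spec$max
      u <- stats::runif(n)
      fc <- (c - a) / (b - a)
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (c - a)),
             b - sqrt((1 - u) * (b - a) * (b - c)))
    },
    normal = ,
    truncated_normal = {
      plo <- stats::pnorm(lo, spec$mean, spec$sd)
      phi <- stats::pnorm(hi, spec$mean, spec$sd)
      stats::qnorm(stats::runif(n, plo, phi), spec$mean, spec$sd)
    },
    lognormal = {
      plo <- stats::plnorm(max(lo, 0), spec$meanlog, spec$sdlog)
      phi <- stats::plnorm(hi, spec$meanlog, spec$sdlog)
      stats::qlnorm(stats::runif(n, plo, phi), spec$meanlog, spec$sdlog)
    },
    empirical = sample(spec$values, n, replace = TRUE)
  )
}

#' Draw joint samples of the model inputs
#'
#' Inputs are mutually independent; each column is drawn from its marginal
#' `dist_spec`. Each input's stream is seeded from the master seed and the
#' input's name, so a given input receives the same draws regardless of the
#' order the specs are listed in — reordering the specs reorders the
#' columns and nothing else.
#'
#' @param specs named list of [dist_spec()] objects, one per input.
#' @param n number of joint draws (rows).
#' @param seed integer seed; required for reproducibility.
#' @return an `n` x `length(specs)` numeric matrix with inputs as columns.
#' @export
sample_inputs <- function(specs, n, seed) {
  stopifnot(n >= 1, length(specs) >= 1)
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    stop("specs must be a named list of dist_spec objects")
  if (!all(vapply(specs, inherits, logical(1), "dist_spec")))
    stop("all specs must be dist_spec objects")
  m <- vapply(names(specs), function(nm) {
    set.seed(name_seed(seed, nm))
    sample_one(specs[[nm]], n)
  }, numeric(n))
  if (n == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(specs)))
  m
}

#' @keywords internal
#' @noRd
name_seed <- function(seed, name) {
  h <- 7
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 65521
  derive_seed(seed, h)
}

#' Read distribution specs from JSON
#'
#' Either a flat object (input name -> spec) or nested per age group
#' (group -> input name -> spec). Each spec is an object with a `family`
#' field plus the family's parameters.
#'
#' @param path path to the distributions JSON file.
#' @return named list of `dist_spec` (flat file) or named list of such
#'   lists (grouped file).
#' @export
read_distributions_json <- function(path) {
  if (!file.exists(path)) stop("distributions file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  as_spec <- function(e) do.call(dist_spec, e)
  grouped <- all(vapply(raw, function(e) is.list(e) && is.null(e$family), logical(1)))
  if (grouped) {
    lapply(raw, function(g) lapply(g, as_spec))
  } else {
    lapply(raw, as_spec)
  }
}
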