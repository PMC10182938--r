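#' Construct a parameter registry
#'
#' The registry holds, per water-quality parameter, its unit, its weight in
#' each index scheme (absent = the scheme does not use the parameter) and the
#' curve id used to rate it. Weights within a scheme must sum to 1 over the
#' parameters that carry one.
#'
#' @param params a data.frame with columns `parameter`, `unit`,
#'   `weight_nsf`, `weight_irwqi`, `curve_id`; weights are NA where a scheme
#'   does not use the parameter.
#' @param check if `TRUE` (default) enforce that each scheme's weights sum
#'   to 1 within 1e-9. Set `FALSE` for deliberately partial registries in
#'   tests.
#' @return an object of class `parameter_registry`.
#' @export
parameter_registry <- function(params, check = TRUE) {
  need <- c("parameter", "unit", "weight_nsf", "weight_irwqi", "curve_id")
  stopifnot(is.data.frame(params), all(need %in% names(params)))
  if (anyDuplicated(params$parameter)) stop("duplicate parameter in registry")
  for (w in c("weight_nsf", "weight_irwqi")) {
    ok <- is.na(params[[w]]) | (params[[w]] >= 0 & params[[w]] <= 1)
    if (!all(ok)) stop("registry weights must lie in [0, 1]")
    if (check) {
      s <- sum(params[[w]], na.rm = TRUE)
      if (abs(s - 1) > 1e-9)
        stop("registry ", w, " weights sum to ", format(s), ", expected 1")
    }
  }
  structure(list(params = params[, need]), class = "parameter_registry")
}

#' @export
print.parameter_registry <- function(x, ...) {
  cat("Parameter registry:", nrow(x$params), "parameters;",
      sum(!is.na(x$params$weight_nsf)), "NSFWQI-weighted,",
      sum(!is.na(x$params$weight_irwqi)), "IRWQISC-weighted\n")
  invisible(x)
}

#' Look up the weight vector of one scheme
#'
#' @param registry a [parameter_registry()].
#' @param scheme `"nsfwqi"` or `"irwqisc"`.
#' @return named numeric vector of weights for the parameters the scheme uses.
#' @export
scheme_weights <- function(registry, scheme = c("nsfwqi", "irwqisc")) {
  scheme <- match.arg(scheme)
  p <- registry$params
  w <- if (scheme == "nsfwqi") p$weight_nsf else p$weight_irwqi
  keep <- !is.na(w)
  stats::setNames(w[keep], p$parameter[keep])
}

#' Packaged default parameter registry
#'
#' Encodes the conventional weight tables of the two indices: nine NSFWQI
#' parameters (fecal coliform 0.16, BOD5 0.11, NO3 0.10, DO 0.17, PO4 0.10,
#' turbidity 0.08, pH 0.11, temperature 0.10, total solids 0.07) and eleven
#' IRWQISC parameters (fecal coliform 0.140, BOD5 0.117, NO3 0.108,
#' DO 0.097, EC 0.096, COD 0.093, NH4 0.090, PO4 0.087, turbidity 0.062,
#' total hardness 0.059, pH 0.051). Both columns sum to 1.
#'
#' Dissolved oxygen is consumed directly as percent saturation; conversion
#' from mg/L via temperature and pressure is out of scope.
#'
#' @return a [parameter_registry()].
#' @export
default_registry <- function() {
  f <- system.file("extdata", "registry.json", package = "wqrisk", mustWork = TRUE)
  read_registry_json(f)
}

#' Read a parameter registry from JSON
#'
#' The file holds one object per parameter with fields `unit`, `nsf_weight`,
#' `irwqi_weight` (either may be null) and `curve_id`.
#'
#' @param path path to the registry JSON file.
#' @return a [parameter_registry()].
#' @export
read_registry_json <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- jsonlite::read_json(path)
  df <- do.call(rbind, lapply(names(raw), function(p) {
    e <- raw[[p]]
    data.frame(parameter = p,
               unit = e$unit %||% "",
               weight_nsf = as.numeric(e$nsf_weight %||% NA_real_),
               weight_irwqi = as.numeric(e$irwqi_weight %||% NA_real_),
               curve_id = e$curve_id %||% p,
               stringsAsFactors = FALSE)
  }))
  parameter_registry(df)
}
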