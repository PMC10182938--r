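#' Exposure constants for one age group
#'
#' Bundles the ingestion-rate / duration / body-weight constants of the
#' chronic-daily-intake model. The averaging time is tied to the exposure
#' duration (`AT = ED * 365` days), which makes the intake independent of
#' `ED` — the two cancel.
#'
#' @param label group name, one of `"children"`, `"teenagers"`, `"adults"`.
#' @param ir daily water ingestion rate, L/day.
#' @param ed exposure duration, years.
#' @param ef exposure frequency, days/year (at most 365).
#' @param bw body weight, kg.
#' @param rfd oral reference dose, mg/kg/day.
#' @return an object of class `age_group_params`.
#' @export
age_group_params <- function(label, ir, ed, ef, bw, rfd) {
  vals <- c(ir = ir, ed = ed, ef = ef, bw = bw, rfd = rfd)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("exposure constants must be strictly positive and finite")
  if (ef > 365) stop("exposure frequency cannot exceed 365 days/year")
  structure(list(label = label, ir = ir, ed = ed, ef = ef, bw = bw,
                 at = ed * 365, rfd = rfd),
            class = "age_group_params")
}

#' @export
print.age_group_params <- function(x, ...) {
  cat(sprintf("Age group '%s': IR %.2f L/day, ED %g yr, EF %g d/yr, BW %.2f kg, RfD %.2f mg/kg/day\n",
              x$label, x$ir, x$ed, x$ef, x$bw, x$rfd))
  invisible(x)
}

#' Default exposure parameter sets
#'
#' Ingestion rates 1.25 / 1.58 / 1.95 L/day, exposure durations 8 / 8 / 52
#' years, exposure frequency 345 days/year for all groups, body weights
#' 16.41 / 39.83 / 77.45 kg, and an oral reference dose for nitrate of
#' 1.6 mg/kg/day.
#'
#' @return named list of [age_group_params()] for children, teenagers and
#'   adults.
#' @export
default_exposure <- function() {
  list(
    children  = age_group_params("children",  ir = 1.25, ed = 8,  ef = 345, bw = 16.41, rfd = 1.6),
    teenagers = age_group_params("teenagers", ir = 1.58, ed = 8,  ef = 345, bw = 39.83, rfd = 1.6),
    adults    = age_group_params("adults",    ir = 1.95, ed = 52, ef = 345, bw = 77.45, rfd = 1.6)
  )
}

#' Read exposure parameter sets from JSON
#'
#' One object per group with fields `ir`, `ed`, `ef`, `bw`, `rfd`.
#'
#' @param path path to the exposure JSON file.
#' @return named list of [age_group_params()].
#' @export
read_exposure_json <- function(path) {
  if (!file.exists(path)) stop("exposure file not found: ", path)
  raw <- jsonlite::read_json(path)
  lapply(stats::setNames(names(raw), names(raw)), function(g) {
    e <- raw[[g]]
    age_group_params(g, ir = e$ir, ed = e$ed, ef = e$ef, bw = e$bw, rfd = e$rfd)
  })
}

#' Chronic daily intake of a waterborne contaminant
#'
#' \deqn{CDI = C \cdot IR \cdot ED \cdot EF / (BW \cdot AT)} in mg/kg/day,
#' where `C` is the concentration in mg/L. With `AT = ED * 365` this
#' simplifies to `C * IR * EF / (BW * 365)` and is independent of `ED`.
#'
#' @param C concentration, mg/L (vectorized, non-negative).
#' @param params an [age_group_params()].
#' @return chronic daily intake, mg/kg/day.
#' @export
cdi <- function(C, params) {
  stopifnot(inherits(params, "age_group_params"))
  if (anyNA(C) || any(!is.finite(C))) stop("non-finite concentration")
  if (any(C < 0)) stop("negative concentration")
  C * params$ir * params$ed * params$ef / (params$bw * params$at)
}

#' Hazard quotient of a waterborne contaminant
#'
#' `HQ = CDI / RfD`. A hazard quotient at or above 1 flags unacceptable
#' non-carcinogenic risk; below 1 the risk is considered negligible to low.
#'
#' @inheritParams cdi
#' @return dimensionless hazard quotient.
#' @export
hq <- function(C, params) {
  if (!is.finite(params$rfd) || params$rfd <= 0) stop("RfD must be positive")
  cdi(C, params) / params$rfd
}

#' Summary risk statistics over a set of concentrations
#'
#' For each age group, evaluates CDI and HQ at every concentration and
#' reports min / mean / max / sample standard deviation (n - 1), rounded to
#' two decimals, plus a flag for whether any HQ reaches 1.
#'
#' @param concentrations numeric vector of concentrations, mg/L (at least 2
#'   for a standard deviation).
#' @param groups named list of [age_group_params()].
#' @return a `risk_summary` data.frame, one row per group x metric (CDI,
#'   HQ), columns `group`, `metric`, `min`, `mean`, `max`, `sd`,
#'   `exceedance` (any HQ >= 1 for that group).
#' @export
summarize_risk <- function(concentrations, groups = default_exposure()) {
  if (length(concentrations) == 0L) stop("empty concentration list")
  if (length(concentrations) < 2L) stop("need at least 2 concentrations for sd")
  rows <- lapply(names(groups), function(g) {
    p <- groups[[g]]
    ci <- cdi(concentrations, p)
    hi <- hq(concentrations, p)
    exc <- any(hi >= 1)
    rbind(
      data.frame(group = g, metric = "CDI", min = min(ci), mean = mean(ci),
                 max = max(ci), sd = stats::sd(ci), exceedance = exc),
      data.frame(group = g, metric = "HQ", min = min(hi), mean = mean(hi),
                 max = max(hi), sd = stats::sd(hi), exceedance = exc)
    )
  })
  out <- do.call(rbind, rows)
  for (col in c("min", "mean", "max", "sd")) {
    out[[paste0(col, "_raw")]] <- out[[col]]
    out[[col]] <- round_half_up(out[[col]], 2)
  }
  class(out) <- c("risk_summary", "data.frame")
  out
}
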