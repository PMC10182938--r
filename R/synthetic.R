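#' Configuration for the synthetic measurement generator
#'
#' The generator emulates a seasonal reservoir monitoring campaign: a fixed
#' station set, four seasons, and one observation per station x season x
#' parameter. Default parameter ranges encode the campaign's reported
#' spans: nitrate 7.8-35.6 mg/L, pH 6.48-7.9, temperature 12-26 degC,
#' turbidity 8-24 NTU, total solids 10-40 mg/L, total hardness 154-530
#' mg CaCO3/L, fecal coliform 0-125 CFU/100 mL, phosphate 0.4-2.3 mg/L,
#' BOD5 2-8.3 mg/L. Ammonium is reported only as a mean (0.012 mg/L) and is
#' generated lognormally around it; dissolved-oxygen saturation, COD and EC
#' are only partially reported (station means), so their defaults bracket
#' those statistics (DO 35-38 percent saturation, COD 10-54 mg/L) with EC
#' set to a plausible brackish-reservoir span (700-1600 uS/cm).
#'
#' @param stations number of stations (default 5).
#' @param periods season labels (default Spring, Summer, Fall, Winter).
#' @param overrides named list of per-parameter overrides; each element a
#'   list with `lo`, `hi` (uniform family) or a full [dist_spec()].
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(stations = 5,
                             periods = c("Spring", "Summer", "Fall", "Winter"),
                             overrides = list()) {
  stopifnot(stations >= 1, length(periods) >= 1)
  defaults <- list(
    no3            = list(lo = 7.8,  hi = 35.6, unit = "mg/L"),
    ph             = list(lo = 6.48, hi = 7.9,  unit = "pH"),
    temperature    = list(lo = 12,   hi = 26,   unit = "degC"),
    turbidity      = list(lo = 8,    hi = 24,   unit = "NTU"),
    ts             = list(lo = 10,   hi = 40,   unit = "mg/L"),
    th             = list(lo = 154,  hi = 530,  unit = "mg CaCO3/L"),
    fecal_coliform = list(lo = 0,    hi = 125,  unit = "CFU/100mL"),
    po4            = list(lo = 0.4,  hi = 2.3,  unit = "mg/L"),
    bod5           = list(lo = 2,    hi = 8.3,  unit = "mg/L"),
    do_sat         = list(lo = 35,   hi = 38,   unit = "% saturation"),
    cod            = list(lo = 10,   hi = 54,   unit = "mg/L"),
    ec             = list(lo = 700,  hi = 1600, unit = "uS/cm"),
    # only the mean (0.012 mg/L) is reported; lognormal with a modest spread
    nh4 = list(spec = dist_spec("lognormal", meanlog = log(0.012) - 0.5^2 / 2,
                                sdlog = 0.5),
               unit = "mg/L")
  )
  for (nm in names(overrides)) {
    o <- overrides[[nm]]
    if (!is.null(o$lo) && !is.null(o$hi) && o$lo > o$hi)
      stop("invalid range for '", nm, "': lo > hi")
    defaults[[nm]] <- utils::modifyList(defaults[[nm]] %||% list(), o)
  }
  for (nm in names(defaults)) {
    d <- defaults[[nm]]
    if (is.null(d$spec) && (is.null(d$lo) || is.null(d$hi) || d$lo > d$hi))
      stop("invalid range for '", nm, "'")
  }
  structure(list(stations = stations, periods = periods, params = defaults),
            class = "generator_config")
}

#' Generate a synthetic measurement table
#'
#' One record per station x period x parameter, drawn independently from
#' each parameter's configured family (uniform over \[lo, hi\] unless a
#' full spec is given). Reproducible under a fixed seed. The defaults give
#' 5 stations x 4 seasons x 13 parameters = 260 records.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a [measurement_table()].
#' @export
generate_measurements <- function(config = generator_config(), seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  stations <- paste0("S", seq_len(config$stations))
  grid <- expand.grid(station = stations, period = config$periods,
                      parameter = names(config$params),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$station, grid$period, grid$parameter), ]
  n_cells <- config$stations * length(config$periods)
  vals <- lapply(names(config$params), function(nm) {
    d <- config$params[[nm]]
    if (!is.null(d$spec)) sample_one(d$spec, n_cells)
    else stats::runif(n_cells, d$lo, d$hi)
  })
  names(vals) <- names(config$params)
  grid$value <- NA_real_
  for (nm in names(vals)) grid$value[grid$parameter == nm] <- vals[[nm]]
  grid$unit <- vapply(grid$parameter,
                      function(nm) config$params[[nm]]$unit %||% "", character(1))
  measurement_table(grid)
}

#' Load a packaged reference fixture
#'
#' Structured records of the published seasonal index tables and the risk
#' summary table, used by acceptance tests:
#' \describe{
#'   \item{table3}{NSFWQI station x season scores and labels, including the
#'     printed per-station and per-season mean cells (`period == "Mean"` /
#'     `station == "Mean"`).}
#'   \item{table4}{the same layout for IRWQISC.}
#'   \item{table5}{per age group, CDI and HQ min/mean/max/sd.}
#' }
#'
#' @param name one of `"table3"`, `"table4"`, `"table5"`.
#' @return a data.frame.
#' @export
load_fixture <- function(name = c("table3", "table4", "table5")) {
  name <- match.arg(name)
  file <- switch(name,
                 table3 = "table3_nsfwqi.csv",
                 table4 = "table4_irwqisc.csv",
                 table5 = "table5_risk.csv")
  path <- system.file("extdata", file, package = "wqrisk", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
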