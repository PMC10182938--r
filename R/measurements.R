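#' Construct and validate a measurement table
#'
#' Long-format station x period x parameter observations, the raw input of
#' the index stage. Values must be non-negative (temperature excepted) and
#' every (station, period, parameter) key must be unique. When a registry is
#' supplied, every parameter key must resolve against it.
#'
#' @param records a data.frame with columns `station`, `period`,
#'   `parameter`, `value`, `unit`.
#' @param registry optional [parameter_registry()] to resolve parameter keys
#'   against.
#' @return the validated data.frame with class `measurement_table`.
#' @export
measurement_table <- function(records, registry = NULL) {
  need <- c("station", "period", "parameter", "value", "unit")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  records <- as.data.frame(records)[, need]
  records$station <- as.character(records$station)
  records$period <- as.character(records$period)
  records$parameter <- as.character(records$parameter)
  if (anyNA(records$value) || any(!is.finite(records$value)))
    stop("measurement values must be finite")
  neg <- records$value < 0 & records$parameter != "temperature"
  if (any(neg))
    stop("negative value for non-temperature parameter(s): ",
         paste(unique(records$parameter[neg]), collapse = ", "))
  key <- paste(records$station, records$period, records$parameter, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (station, period, parameter) key in measurement table")
  if (!is.null(registry)) {
    unknown <- setdiff(unique(records$parameter), registry$params$parameter)
    if (length(unknown))
      stop("parameter(s) not in registry: ", paste(unknown, collapse = ", "))
  }
  class(records) <- c("measurement_table", "data.frame")
  records
}

#' Read a measurement table from CSV
#'
#' Expects UTF-8 with header `station,period,parameter,value,unit`.
#'
#' @param path path to the measurements CSV.
#' @inheritParams measurement_table
#' @return a `measurement_table`.
#' @export
read_measurements_csv <- function(path, registry = NULL) {
  if (!file.exists(path)) stop("measurements file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  measurement_table(df, registry = registry)
}

#' Write a measurement table to CSV
#'
#' @param table a `measurement_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_measurements_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
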