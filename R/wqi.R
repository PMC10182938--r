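#' NSFWQI: weighted arithmetic aggregation of sub-indices
#'
#' Computes \eqn{\sum_i Q_i W_i / \sum_i W_i} over the parameters present in
#' `subindices` that carry an NSF weight in the registry. The explicit
#' division by the sum of used weights makes the score robust to missing
#' parameters: weights renormalize over what is present.
#'
#' @param subindices named numeric vector, parameter -> sub-index in
#'   \[0, 100\].
#' @param registry a [parameter_registry()].
#' @return the index score, a scalar in \[0, 100\].
#' @examples
#' reg <- default_registry()
#' q <- setNames(rep(70, 9), names(scheme_weights(reg, "nsfwqi")))
#' nsfwqi(q, reg)  # 70
#' @export
nsfwqi <- function(subindices, registry) {
  w <- scheme_weights(registry, "nsfwqi")
  weighted_index(subindices, w, geometric = FALSE, q_min = 0)
}

#' IRWQISC: weighted geometric aggregation of sub-indices
#'
#' Computes \eqn{(\prod_i I_i^{W_i})^{1/\gamma}} with
#' \eqn{\gamma = \sum_i W_i} over the parameters present that carry an
#' IRWQISC weight. Evaluated in the log domain for numerical stability.
#' Sub-indices must be at least 1 (the scheme's rating floor); a value of 0
#' or below makes the geometric mean degenerate and is an error.
#'
#' @inheritParams nsfwqi
#' @return the index score, a scalar in \[1, 100\].
#' @export
irwqi <- function(subindices, registry) {
  w <- scheme_weights(registry, "irwqisc")
  weighted_index(subindices, w, geometric = TRUE, q_min = 1)
}

#' @keywords internal
#' @noRd
weighted_index <- function(subindices, weights, geometric, q_min) {
  if (length(subindices) == 0L) stop("empty sub-index set")
  if (is.null(names(subindices)) || any(!nzchar(names(subindices))))
    stop("sub-indices must be named by parameter")
  if (anyNA(subindices) || any(!is.finite(subindices)))
    stop("non-finite sub-index")
  use <- intersect(names(subindices), names(weights))
  if (length(use) == 0L) stop("no weighted parameter present in sub-index set")
  q <- subindices[use]
  if (any(q > 100) || any(q < if (geometric) 0 else q_min))
    stop("sub-index outside [", q_min, ", 100]")
  if (geometric && any(q <= 0))
    stop("sub-index <= 0: geometric aggregation undefined")
  w <- weights[use]
  if (geometric) {
    exp(sum(w * log(q)) / sum(w))
  } else {
    sum(w * q) / sum(w)
  }
}

#' Classify an index score into its quality band
#'
#' Band edges follow the published classification tables, made contiguous
#' and upper-inclusive so every score in \[0, 100\] receives a label.
#' NSFWQI: (90, 100\] "Excellent", (70, 90\] "Good", (50, 70\] "Medium",
#' (25, 50\] "Bad", \[0, 25\] "Very bad". IRWQISC: less than 15 "Very bad"
#' (the published table leaves this region unlabelled; the next band down is
#' extrapolated), then "Bad" below 30, "Relatively bad" below 45, "Medium"
#' below 55.1, "Relatively good" up to 70, "Good" up to 85 and "Very good"
#' above 85.
#'
#' @param score numeric vector of scores in \[0, 100\].
#' @param scheme `"nsfwqi"` or `"irwqisc"`.
#' @return character vector of class labels.
#' @export
classify_wqi <- function(score, scheme = c("nsfwqi", "irwqisc")) {
  scheme <- match.arg(scheme)
  if (anyNA(score) || any(score < 0 | score > 100))
    stop("score out of [0, 100]")
  if (scheme == "nsfwqi") {
    vapply(score, function(s) {
      if (s <= 25) "Very bad"
      else if (s <= 50) "Bad"
      else if (s <= 70) "Medium"
      else if (s <= 90) "Good"
      else "Excellent"
    }, character(1))
  } else {
    vapply(score, function(s) {
      if (s < 15) "Very bad"
      else if (s < 30) "Bad"
      else if (s < 45) "Relatively bad"
      else if (s < 55.1) "Medium"
      else if (s <= 70) "Relatively good"
      else if (s <= 85) "Good"
      else "Very good"
    }, character(1))
  }
}

#' Compute index scores for every station and period of a measurement table
#'
#' Rates each observation on its parameter's curve, then aggregates the
#' sub-indices of each (station, period) cell with the scheme's weights.
#' Parameters without a weight in the scheme are ignored; missing parameters
#' renormalize the weights over what is present.
#'
#' @param measurements a [measurement_table()].
#' @param registry a [parameter_registry()].
#' @param curves named list of [rating_curve()] objects keyed by curve id.
#' @param scheme `"nsfwqi"` or `"irwqisc"`.
#' @return a `wqi_result` data.frame with columns `scheme`, `station`,
#'   `period`, `score`, `label`, `used_weight_sum`, plus the per-cell
#'   sub-index map in attribute `"subindices"`.
#' @export
compute_wqi <- function(measurements, registry, curves,
                        scheme = c("nsfwqi", "irwqisc")) {
  scheme <- match.arg(scheme)
  measurements <- measurement_table(as.data.frame(measurements), registry = registry)
  w <- scheme_weights(registry, scheme)
  p <- registry$params
  curve_of <- stats::setNames(p$curve_id, p$parameter)
  missing_curves <- setdiff(unname(curve_of[names(w)]), names(curves))
  if (length(missing_curves))
    stop("no rating curve for curve id(s): ", paste(missing_curves, collapse = ", "))

  cells <- unique(measurements[, c("station", "period")])
  sub_maps <- vector("list", nrow(cells))
  out <- cells
  out$scheme <- scheme
  out$score <- NA_real_
  out$used_weight_sum <- NA_real_
  for (i in seq_len(nrow(cells))) {
    m <- measurements[measurements$station == cells$station[i] &
                        measurements$period == cells$period[i], ]
    m <- m[m$parameter %in% names(w), ]
    if (nrow(m) == 0L)
      stop("no scheme-weighted parameter measured at station ",
           cells$station[i], ", period ", cells$period[i])
    q <- vapply(seq_len(nrow(m)), function(j) {
      rate_parameter(m$value[j], curves[[curve_of[[m$parameter[j]]]]])
    }, numeric(1))
    names(q) <- m$parameter
    if (scheme == "irwqisc") q <- pmax(q, 1) # rating floor of the 1-100 scale
    out$score[i] <- if (scheme == "nsfwqi") nsfwqi(q, registry) else irwqi(q, registry)
    out$used_weight_sum[i] <- sum(w[names(q)])
    sub_maps[[i]] <- q
  }
  out$label <- classify_wqi(out$score, scheme)
  out <- out[, c("scheme", "station", "period", "score", "label", "used_weight_sum")]
  attr(out, "subindices") <- sub_maps
  class(out) <- c("wqi_result", "data.frame")
  out
}

#' Aggregate index scores over stations or periods
#'
#' Arithmetic mean of the member scores within each group, reported rounded
#' half-away-from-zero at one decimal (the convention of the printed
#' seasonal tables); the quality label is re-derived from the unrounded
#' mean.
#'
#' @param results a data.frame of index results sharing one scheme, with
#'   columns `scheme`, `station`, `period`, `score`.
#' @param by `"station"` (mean over periods per station) or `"period"`
#'   (mean over stations per period).
#' @return data.frame with columns `group`, `mean_score` (1 decimal),
#'   `label`, and unrounded `mean_raw`.
#' @export
aggregate_scores <- function(results, by = c("station", "period")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(results), nrow(results) > 0)
  scheme <- unique(results$scheme)
  if (length(scheme) != 1L) stop("results mix schemes; aggregate one scheme at a time")
  groups <- split(results$score, results[[by]])
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  raw <- vapply(groups, mean, numeric(1))
  data.frame(group = names(groups),
             mean_score = round_half_up(raw, 1),
             label = classify_wqi(raw, scheme),
             mean_raw = unname(raw),
             stringsAsFactors = FALSE, row.names = NULL)
}
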