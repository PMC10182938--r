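#' Monte Carlo propagation of the hazard quotient
#'
#' Samples the stochastic inputs of the intake model (`C`, `IR`, `EF`, `BW`;
#' any not given a spec is held at the age group's point value), evaluates
#' the hazard quotient row by row, and summarizes the resulting
#' distribution. Percentiles use the linear-interpolation empirical-quantile
#' convention (R's default type 7) — stated because conventions differ
#' across software.
#'
#' @param specs named list of [dist_spec()] for any of `C`, `IR`, `EF`,
#'   `BW`. A spec for `C` is required (it has no group default).
#' @param params an [age_group_params()] supplying defaults for inputs
#'   without a spec and the reference dose.
#' @param n number of draws (default 50000).
#' @param seed integer seed, required.
#' @param probs percentile levels to report (default 5, 50, 95).
#' @return an object of class `mc_result`: list with `n`, `seed`, `group`,
#'   `mean`, `sd`, `percentiles` (named vector), `p_exceed`
#'   (fraction of draws with HQ >= 1) and the draw vector `hq`.
#' @export
mc_hq <- function(specs, params, n = 50000, seed, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(params, "age_group_params"), n >= 1)
  if (missing(seed)) stop("seed is required for a reproducible simulation")
  allowed <- c("C", "IR", "EF", "BW", "ED")
  unknown <- setdiff(names(specs), allowed)
  if (length(unknown))
    stop("unknown model input(s): ", paste(unknown, collapse = ", "))
  if (is.null(specs$C)) stop("a distribution spec for C is required")
  defaults <- list(IR = params$ir, EF = params$ef, BW = params$bw, ED = params$ed)
  full <- specs
  for (nm in names(defaults)) {
    if (is.null(full[[nm]])) full[[nm]] <- dist_spec("point", value = defaults[[nm]])
  }
  full <- full[c("C", "IR", "EF", "BW", "ED")]
  draws <- sample_inputs(full, n, seed)
  # AT = ED * 365 by construction, so ED cancels and HQ = C IR EF / (BW 365 RfD)
  hq_draws <- draws[, "C"] * draws[, "IR"] * draws[, "EF"] /
    (draws[, "BW"] * 365 * params$rfd)
  if (any(!is.finite(hq_draws))) stop("non-finite hazard quotient draw")
  pct <- stats::quantile(hq_draws, probs = probs, type = 7, names = FALSE)
  structure(list(
    n = n, seed = as.integer(seed), group = params$label,
    mean = mean(hq_draws), sd = stats::sd(hq_draws),
    percentiles = stats::setNames(pct, paste0("p", probs * 100)),
    p_exceed = mean(hq_draws >= 1),
    hq = hq_draws
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo HQ, group '%s', n = %d (seed %d)\n", x$group, x$n, x$seed))
  cat("  percentiles:", paste(names(x$percentiles),
                              sprintf("%.3f", x$percentiles), collapse = "  "), "\n")
  cat(sprintf("  mean %.3f, sd %.3f, P(HQ >= 1) = %.3f\n", x$mean, x$sd, x$p_exceed))
  invisible(x)
}

#' Tabulate a Monte Carlo result without the draw vector
#'
#' @param x an `mc_result`.
#' @return one-row data.frame suitable for CSV/JSON reports.
#' @export
mc_result_table <- function(x) {
  stopifnot(inherits(x, "mc_result"))
  df <- data.frame(group = x$group, n = x$n, seed = x$seed,
                   mean = x$mean, sd = x$sd, p_exceed = x$p_exceed)
  for (nm in names(x$percentiles)) df[[nm]] <- unname(x$percentiles[nm])
  df
}
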