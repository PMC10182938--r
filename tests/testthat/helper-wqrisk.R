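# Shared fixtures, built in code: synthetic curves and registries so that
# engine tests never depend on the packaged curve tables.

linear_curve <- function(parameter = "demo", x0 = 0, x1 = 100, q0 = 100, q1 = 0) {
  rating_curve(parameter, c(x0, x1), c(q0, q1))
}

# a registry whose two weight columns are identical, for AM-GM comparisons
equal_weight_registry <- function(params, weights) {
  parameter_registry(data.frame(
    parameter = params, unit = "u",
    weight_nsf = weights, weight_irwqi = weights,
    curve_id = params, stringsAsFactors = FALSE
  ), check = abs(sum(weights) - 1) < 1e-9)
}

# random positive weights summing to 1 over n parameters
random_registry <- function(n, seed) {
  set.seed(seed)
  w <- stats::runif(n, 0.2, 1)
  w <- w / sum(w)
  equal_weight_registry(paste0("p", seq_len(n)), w)
}

# brute-force piecewise-linear interpolation: explicit segment search,
# independent of stats::approx
interp_oracle <- function(value, x, q) {
  vapply(value, function(v) {
    if (v <= x[1]) return(q[1])
    if (v >= x[length(x)]) return(q[length(q)])
    i <- max(which(x <= v))
    if (x[i] == v) return(q[i])
    q[i] + (q[i + 1] - q[i]) * (v - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# fixture rows that are plain member cells (not printed mean cells)
fixture_members <- function(tab) {
  tab[tab$station != "Mean" & tab$period != "Mean", ]
}

# turn fixture member cells into the data.frame shape aggregate_scores eats
fixture_as_results <- function(tab, scheme) {
  m <- fixture_members(tab)
  data.frame(scheme = scheme, station = m$station, period = m$period,
             score = m$score, stringsAsFactors = FALSE)
}
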