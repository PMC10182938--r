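# Closed-form oracles ------------------------------------------------------

# Ishigami function f = sin x1 + a sin^2 x2 + b x3^4 sin x1, x_i ~ U(-pi, pi)
ishigami <- function(M, a = 7, b = 0.1) {
  sin(M[, 1]) + a * sin(M[, 2])^2 + b * M[, 3]^4 * sin(M[, 1])
}
ishigami_truth <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  list(V = V, S = c(V1, V2, 0) / V,
       T = c(V1 + V13, V2, V13) / V,
       S13 = V13 / V)
}

uniform_specs <- function(k, lo = -pi, hi = pi) {
  setNames(lapply(seq_len(k), function(i) dist_spec("uniform", min = lo, max = hi)),
           paste0("x", seq_len(k)))
}

# --------------------------------------------------------------------------

test_that("the Saltelli design has the stated structure and determinism", {
  specs <- uniform_specs(2, 0, 1)
  d <- saltelli_design(specs, N = 4, seed = 1)
  expect_equal(d$N * (2 * d$k + 2), 24) # N (2k + 2) evaluations
  expect_equal(d$AB[[1]][, 2], d$A[, 2])
  expect_equal(d$AB[[1]][, 1], d$B[, 1])
  expect_equal(d$BA[[2]][, 2], d$A[, 2])
  expect_equal(d$BA[[2]][, 1], d$B[, 1])
  d2 <- saltelli_design(specs, N = 4, seed = 1)
  expect_identical(d$A, d2$A)
  expect_identical(d$B, d2$B)
  expect_false(isTRUE(all.equal(d$A, d$B))) # A and B independent draws
  expect_error(saltelli_design(specs, N = 1, seed = 1), "at least 2")
  expect_error(saltelli_design(specs["x1"], N = 4, seed = 1), "at least 2 inputs")
})

test_that("additive models recover analytic first-order indices, sum to 1, no interactions", {
  a_coef <- c(2, 1, 0.5)
  vx <- (2 * pi)^2 / 12 # Var of U(-pi, pi)
  V <- sum(a_coef^2) * vx
  S_true <- a_coef^2 * vx / V
  d <- saltelli_design(uniform_specs(3), N = 2^12, seed = 101)
  res <- sobol_indices(d, function(M) M %*% a_coef, n_boot = 100)
  for (i in 1:3) {
    expect_lt(abs(res$first$S[i] - S_true[i]), 3 * res$first$S_se[i] + 0.01)
    expect_lt(abs(res$first$T[i] - S_true[i]), 3 * res$first$T_se[i] + 0.01)
  }
  expect_lt(abs(sum(res$first$S) - 1), 0.05)
  expect_true(all(abs(res$second$Sij) < 3 * res$second$Sij_se + 0.01))
})

test_that("Ishigami indices match the closed-form decomposition", {
  tr <- ishigami_truth()
  d <- saltelli_design(uniform_specs(3), N = 2^12, seed = 202)
  res <- sobol_indices(d, ishigami, n_boot = 100)
  for (i in 1:3) {
    expect_lt(abs(res$first$S[i] - tr$S[i]), 3 * res$first$S_se[i] + 0.01)
    expect_lt(abs(res$first$T[i] - tr$T[i]), 3 * res$first$T_se[i] + 0.01)
  }
  s13 <- res$second[res$second$input_i == "x1" & res$second$input_j == "x3", ]
  expect_lt(abs(s13$Sij - tr$S13), 3 * s13$Sij_se + 0.02)
  # x2 interacts with nothing
  s12 <- res$second[res$second$input_j == "x2" | res$second$input_i == "x2", ]
  expect_true(all(abs(s12$Sij) < 3 * s12$Sij_se + 0.02))
})

test_that("estimates converge toward the closed forms as N grows", {
  tr <- ishigami_truth()
  err <- vapply(c(2^8, 2^12), function(N) {
    d <- saltelli_design(uniform_specs(3), N = N, seed = 303)
    res <- sobol_indices(d, ishigami, n_boot = 0)
    max(abs(res$first$S - tr$S), abs(res$first$T - tr$T))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("degenerate outputs yield all-zero indices with a warning", {
  d <- saltelli_design(uniform_specs(2, 0, 1), N = 64, seed = 5)
  expect_warning(res <- sobol_indices(d, function(M) rep(4.2, nrow(M))),
                 "degenerate")
  expect_equal(res$first$S, c(0, 0))
  expect_equal(res$first$T, c(0, 0))
  expect_equal(res$second$Sij, 0)
  expect_error(sobol_indices(d, function(M) rep(NA_real_, nrow(M))), "non-finite")
  expect_error(sobol_indices(d, function(M) 1), "one output per row")
})

test_that("permuting the input order permutes the indices (label equivariance)", {
  specs <- list(p = dist_spec("uniform", min = 0, max = 1),
                q = dist_spec("uniform", min = 0, max = 3),
                r = dist_spec("uniform", min = 0, max = 2))
  model_named <- function(M) M[, "p"] + 2 * M[, "q"] * M[, "r"]
  r1 <- sobol_indices(saltelli_design(specs, 512, seed = 9), model_named, n_boot = 0)
  r2 <- sobol_indices(saltelli_design(specs[c("r", "p", "q")], 512, seed = 9),
                      model_named, n_boot = 0)
  o1 <- setNames(r1$first$S, r1$first$input)
  o2 <- setNames(r2$first$S, r2$first$input)
  expect_equal(o1[c("p", "q", "r")], o2[c("p", "q", "r")], tolerance = 1e-12)
})

test_that("hazard-quotient sensitivity isolates the stochastic input and is reproducible", {
  ch <- default_exposure()$children
  res <- hq_sensitivity(list(C = dist_spec("uniform", min = 7.8, max = 35.6)),
                        ch, N = 1024, seed = 11, n_boot = 50)
  sC <- res$first[res$first$input == "C", ]
  expect_gt(sC$S, 0.95)
  expect_gt(sC$T, 0.95)
  others <- res$first[res$first$input != "C", ]
  expect_true(all(abs(others$S) < 0.05) && all(abs(others$T) < 0.05))
  res2 <- hq_sensitivity(list(C = dist_spec("uniform", min = 7.8, max = 35.6)),
                         ch, N = 1024, seed = 11, n_boot = 50)
  expect_identical(res$first, res2$first)
  expect_error(hq_sensitivity(list(IR = dist_spec("point", value = 1)), ch,
                              N = 64, seed = 1), "spec for C")
})

test_that("first-order ranks of the multiplicative model follow the log-variance oracle", {
  # HQ is a product of independent factors; on the log scale the variance
  # decomposes additively, so inputs rank by Var(log X_i). Use lognormal
  # inputs with distinct sdlog to fix the expected ranking a priori.
  ch <- default_exposure()$children
  sdlogs <- c(C = 0.5, IR = 0.3, EF = 0.2, BW = 0.1)
  means <- c(C = log(18), IR = log(ch$ir), EF = log(300), BW = log(ch$bw))
  specs <- lapply(names(sdlogs), function(nm)
    dist_spec("lognormal", meanlog = means[[nm]], sdlog = sdlogs[[nm]]))
  names(specs) <- names(sdlogs)
  res <- hq_sensitivity(specs, ch, N = 2^12, seed = 23, n_boot = 0)
  got <- res$first$input[order(-res$first$S)]
  expect_equal(got, c("C", "IR", "EF", "BW"))
})

test_that("S_i <= T_i within bootstrap noise across tested models", {
  d <- saltelli_design(uniform_specs(3), N = 2^11, seed = 404)
  for (model in list(ishigami,
                     function(M) M %*% c(1, 2, 3),
                     function(M) exp(M[, 1]) * (1 + 0.5 * M[, 2] * M[, 3]))) {
    res <- sobol_indices(d, model, n_boot = 60)
    expect_true(all(res$first$S <= res$first$T +
                      3 * sqrt(res$first$S_se^2 + res$first$T_se^2) + 1e-6))
  }
})
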