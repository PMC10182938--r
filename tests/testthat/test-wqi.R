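reg_default <- default_registry()

test_that("nsfwqi is a renormalized weighted arithmetic mean", {
  nsf_params <- names(scheme_weights(reg_default, "nsfwqi"))
  expect_equal(nsfwqi(setNames(rep(70, 9), nsf_params), reg_default), 70)
  expect_equal(nsfwqi(c(no3 = 42), reg_default), 42) # single parameter renormalizes
  # brute-force weighted-sum oracle with the published weights
  w <- scheme_weights(reg_default, "nsfwqi")
  for (seed in 1:5) {
    set.seed(seed)
    q <- setNames(runif(9, 0, 100), nsf_params)
    acc <- 0; wacc <- 0
    for (p in nsf_params) { acc <- acc + q[[p]] * w[[p]]; wacc <- wacc + w[[p]] }
    expect_equal(nsfwqi(q, reg_default), acc / wacc, tolerance = 1e-12)
  }
})

test_that("irwqi is a weighted geometric mean computed in the log domain", {
  ir_params <- names(scheme_weights(reg_default, "irwqisc"))
  expect_equal(irwqi(setNames(rep(55, 11), ir_params), reg_default), 55)
  two <- equal_weight_registry(c("a", "b"), c(0.5, 0.5))
  expect_equal(irwqi(c(a = 25, b = 100), two), 50) # sqrt(25 * 100)
  w <- scheme_weights(reg_default, "irwqisc")
  for (seed in 1:5) {
    set.seed(seed)
    q <- setNames(runif(11, 1, 100), ir_params)
    oracle <- exp(sum(w[ir_params] * log(q)) / sum(w[ir_params]))
    expect_equal(irwqi(q, reg_default), oracle, tolerance = 1e-9)
  }
})

test_that("index aggregation rejects bad input", {
  expect_error(nsfwqi(setNames(numeric(0), character(0)), reg_default), "empty")
  expect_error(nsfwqi(c(no3 = 120), reg_default), "outside")
  expect_error(nsfwqi(c(zzz = 50), reg_default), "no weighted parameter")
  expect_error(irwqi(c(no3 = -3), reg_default), "outside|undefined")
  two <- equal_weight_registry(c("a", "b"), c(0.5, 0.5))
  expect_error(irwqi(c(a = 0, b = 50), two), "undefined|outside")
})

test_that("identity, AM-GM, monotonicity and range preservation hold", {
  for (seed in 1:20) {
    reg <- random_registry(n = 5 + seed %% 4, seed = seed)
    params <- reg$params$parameter
    set.seed(seed + 1000)
    # identity: constant sub-indices return that constant for any weights
    qc <- runif(1, 1, 100)
    expect_equal(nsfwqi(setNames(rep(qc, length(params)), params), reg), qc,
                 tolerance = 1e-9)
    expect_equal(irwqi(setNames(rep(qc, length(params)), params), reg), qc,
                 tolerance = 1e-9)
    # AM-GM with identical sub-indices and weights; equality iff all equal
    q <- setNames(runif(length(params), 1, 100), params)
    expect_lt(irwqi(q, reg), nsfwqi(q, reg))
    # monotonicity: raising one sub-index never lowers either index
    i <- sample(length(params), 1)
    q2 <- q; q2[i] <- min(100, q2[i] + runif(1, 0, 100 - q2[i]))
    expect_gte(nsfwqi(q2, reg), nsfwqi(q, reg))
    expect_gte(irwqi(q2, reg), irwqi(q, reg))
    # range preservation
    for (f in c(nsfwqi, irwqi)) {
      s <- f(q, reg)
      expect_gte(s, min(q)); expect_lte(s, max(q))
    }
  }
})

test_that("classification matches the band tables and printed pairs", {
  expect_equal(classify_wqi(49.32, "nsfwqi"), "Bad")
  expect_equal(classify_wqi(19.27, "irwqisc"), "Bad")
  expect_equal(classify_wqi(70, "nsfwqi"), "Medium")    # bands upper-inclusive
  expect_equal(classify_wqi(70.05, "nsfwqi"), "Good")
  expect_equal(classify_wqi(55.05, "irwqisc"), "Medium") # 55.1 opens the next band
  expect_equal(classify_wqi(55.1, "irwqisc"), "Relatively good")
  expect_error(classify_wqi(101, "nsfwqi"), "out of")
  expect_error(classify_wqi(-0.5, "irwqisc"), "out of")

  # totality/consistency vs an independent cut()-based band oracle
  set.seed(42)
  s <- runif(10000, 0, 100)
  nsf_oracle <- as.character(cut(s, c(-Inf, 25, 50, 70, 90, Inf),
                                 labels = c("Very bad", "Bad", "Medium", "Good", "Excellent"),
                                 right = TRUE))
  expect_equal(classify_wqi(s, "nsfwqi"), nsf_oracle)
  ir_oracle <- ifelse(s < 15, "Very bad",
               ifelse(s < 30, "Bad",
               ifelse(s < 45, "Relatively bad",
               ifelse(s < 55.1, "Medium",
               ifelse(s <= 70, "Relatively good",
               ifelse(s <= 85, "Good", "Very good"))))))
  expect_equal(classify_wqi(s, "irwqisc"), ir_oracle)

  # every printed (score, label) pair in the packaged tables is reproduced
  t3 <- load_fixture("table3")
  expect_equal(classify_wqi(t3$score, "nsfwqi"), t3$label)
  t4 <- load_fixture("table4")
  expect_equal(classify_wqi(t4$score, "irwqisc"), t4$label)
})

test_that("compute_wqi rates, renormalizes over missing parameters, and labels", {
  reg <- equal_weight_registry(c("a", "b"), c(0.6, 0.4))
  curves <- list(a = linear_curve("a"), b = linear_curve("b"))
  m <- measurement_table(data.frame(
    station = c("S1", "S1", "S2"), period = "Spring",
    parameter = c("a", "b", "a"), value = c(20, 60, 50), unit = "u"))
  res <- compute_wqi(m, reg, curves, "nsfwqi")
  # a rates to 80, b to 40: 0.6*80 + 0.4*40 = 64
  expect_equal(res$score[res$station == "S1"], 64)
  expect_equal(res$used_weight_sum[res$station == "S1"], 1)
  # S2 misses b: renormalizes onto a alone
  expect_equal(res$score[res$station == "S2"], 50)
  expect_equal(res$used_weight_sum[res$station == "S2"], 0.6)
  expect_equal(res$label, classify_wqi(res$score, "nsfwqi"))
  expect_error(compute_wqi(m, reg, curves["a"], "nsfwqi"), "no rating curve")
})
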