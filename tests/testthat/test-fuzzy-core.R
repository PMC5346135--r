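test_that("trapezoid evaluation matches the piecewise-linear definition", {
  mf <- trap_mf(8, 10, 20, 25)
  expect_equal(membership_grade(mf, 12), 1.0)
  expect_equal(membership_grade(mf, 9), 0.5)
  expect_equal(membership_grade(mf, 30), 0.0)
  # vectorised evaluation agrees with a scalar hand formula everywhere
  xs <- seq(0, 40, by = 0.37)
  expect_equal(membership_grade(mf, xs),
               vapply(xs, oracle_trap, numeric(1), a = 8, b = 10, c = 20, d = 25))
  # degenerate shoulder/triangle shapes stay within [0, 1]
  sh <- trap_mf(0, 0, 5, 10)
  expect_equal(membership_grade(sh, 0), 1.0)
  tri <- trap_mf(2, 5, 5, 8)
  expect_equal(membership_grade(tri, 5), 1.0)
  expect_equal(membership_grade(tri, 3.5), 0.5)
  expect_error(trap_mf(5, 4, 6, 7), "a <= b <= c <= d")
})

test_that("fuzzification is sum-to-one and clamps out-of-range inputs", {
  parts <- default_partitions("adult")
  # apneic extreme: fully VL
  g <- fuzzify(0, parts$rr)
  expect_equal(g[["VL"]], 1.0)
  expect_equal(sum(g), 1.0)
  # interior of the N plateau
  expect_equal(fuzzify(38, parts$etco2)[["N"]], 1.0)
  # transition zone: hand-evaluated trapezoid values, two adjacent labels
  g30 <- fuzzify(30, parts$etco2)  # L falls 28->33, N rises 28->33
  expect_equal(g30[["L"]], 3 / 5)
  expect_equal(g30[["N"]], 2 / 5)
  expect_equal(sum(g30 > 0), 2)
  # sum-to-one property over random draws in every partition and mode
  set.seed(11)
  for (mode in age_modes()) {
    for (p in default_partitions(mode)) {
      xs <- runif(2500, p$range[1], p$range[2])
      tot <- vapply(xs, function(x) sum(fuzzify(x, p)), numeric(1))
      expect_true(all(abs(tot - 1) < 1e-9))
    }
  }
  # clamping: values beyond the range behave like the range ends
  expect_equal(fuzzify(120, parts$spo2), fuzzify(110, parts$spo2))
  expect_equal(fuzzify(-5, parts$rr), fuzzify(0, parts$rr))
  expect_error(fuzzify(NaN, parts$rr), class = "ipindex_invalid_sample")
})

test_that("rule evaluation uses min for AND and max for aggregation", {
  parts <- default_partitions("adult")
  grades <- list(
    etco2 = fuzzify(70, parts$etco2),  # fully VH
    rr = fuzzify(40, parts$rr),        # fully VH
    spo2 = fuzzify(98, parts$spo2),    # fully N
    pr = fuzzify(130, parts$pr))       # fully H
  rules <- data.frame(etco2 = "VH", rr = "VH", spo2 = "N",
                      consequent = 2L)
  act <- evaluate_rules(grades, rules)
  expect_equal(act[["2"]], 1.0)
  expect_equal(sum(act), 1.0)
  # all grades zero for the referenced labels -> zero activation
  none <- evaluate_rules(list(etco2 = c(VH = 0), rr = c(VH = 0)),
                         data.frame(etco2 = "VH", rr = "VH", consequent = 5L))
  expect_true(all(none == 0))
  # two rules sharing a consequent aggregate with max
  two <- evaluate_rules(
    list(a = c(X = 0.3, Y = 0.7)),
    data.frame(a = c("X", "Y"), consequent = c(4L, 4L)))
  expect_equal(two[["4"]], 0.7)
  # partial antecedents take the min across clauses
  mixed <- evaluate_rules(
    list(a = c(X = 0.4), b = c(Z = 0.9)),
    data.frame(a = "X", b = "Z", consequent = 6L))
  expect_equal(mixed[["6"]], 0.4)
  # unknown label is a configuration error
  expect_error(
    evaluate_rules(list(a = c(X = 1)), data.frame(a = "Q", consequent = 1L)),
    "unknown label")
})

test_that("centroid defuzzification is exact on symmetric cases and errors when nothing fires", {
  expect_equal(defuzzify_centroid(c("10" = 1)), 10.0)
  expect_equal(defuzzify_centroid(c("4" = 0.5, "6" = 0.5)), 5.0)
  expect_equal(defuzzify_centroid(c("7" = 1)), 7.0)  # crisp idempotence
  expect_error(defuzzify_centroid(c("3" = 0)), class = "ipindex_no_rule_fired")
})

test_that("centroid agrees with dense numerical integration on random activation maps", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    lv <- sort(sample(1:10, k))
    a <- stats::setNames(round(runif(k, 0.05, 1), 3), as.character(lv))
    expect_equal(defuzzify_centroid(a), oracle_centroid(a), tolerance = 1e-6)
  }
  expect_equal(defuzzify_centroid(c("5" = 0.8, "8" = 0.3)),
               oracle_centroid(c("5" = 0.8, "8" = 0.3)), tolerance = 1e-6)
})

test_that("the fuzzify/rules/centroid pipeline is continuous in its inputs", {
  cal <- adult_cal()
  set.seed(9)
  for (i in 1:40) {
    x <- c(etco2 = runif(1, 0, 100), rr = runif(1, 0, 60),
           spo2 = runif(1, 70, 100), pr = runif(1, 30, 180))
    base <- compute_ipi(x[1], x[2], x[3], x[4], calibration = cal)$ipi_raw
    for (j in 1:4) {
      y <- x
      y[j] <- y[j] + 1e-6
      pert <- compute_ipi(y[1], y[2], y[3], y[4], calibration = cal)$ipi_raw
      expect_lt(abs(pert - base), 1e-3)
    }
  }
})

test_that("malformed partitions are rejected", {
  # gap between sets breaks sum-to-one
  expect_error(
    fuzzy_partition("x", list(L = trap_mf(0, 0, 2, 3), H = trap_mf(4, 5, 10, 10)),
                    c(0, 10)),
    "transition edge")
  # no overlap at the shared edge
  expect_error(
    fuzzy_partition("x", list(L = trap_mf(0, 0, 5, 5), H = trap_mf(5, 5, 10, 10)),
                    c(0, 10)),
    "overlap")
})
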